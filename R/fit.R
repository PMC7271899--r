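# The four-step fit heuristic: (1) draw an ensemble from the prior and
# anneal the tempered posterior up a beta ladder; (2) select a handful of
# elite samples and polish them with Powell's method; (3) reseed the
# ensemble around the optima (allocation weighted by tempered posterior,
# Gaussian jitter to keep the stretch proposal valid) and sample; (4)
# terminate when sampling stops discovering better local maxima.

#' Fit by annealed ensemble MCMC with local optimization
#'
#' @param logpost_fn Function of a coordinate vector returning
#'   `c(log_prior, log_lik)` (so that annealing can temper the likelihood
#'   alone). The log-posterior is their sum.
#' @param prior_sampler Function of one integer n returning an `n x
#'   n_dims` matrix of draws from the prior.
#' @param config A [kai_config()]; the `"test"` profile resolves
#'   `n_walkers` to `2 * n_dims + 2`.
#' @return List with `best` (coordinates), `best_log_posterior`, the
#'   post-analysis `chain` (thinned last `post_window` steps: steps x
#'   walkers x dims), `chain_log_posterior`, `generations`,
#'   `converged` (FALSE when the generation budget ran out first), and
#'   `acceptance` of the final sampling run.
#' @export
kai_fit <- function(logpost_fn, prior_sampler, config = kai_config("test")) {
  stopifnot(inherits(config, "kai_config"))
  probe <- prior_sampler(2L)
  n_dims <- ncol(probe)
  nw <- config$n_walkers
  if (is.na(nw)) nw <- 2L * n_dims + 2L
  if (nw <= n_dims) {
    stop("the number of walkers must exceed the number of free parameters")
  }
  lp_total <- function(theta) sum(logpost_fn(theta))

  # ---- initialization: draw from the prior, keep finite-posterior draws
  positions <- matrix(NA_real_, 0, n_dims)
  lps <- numeric(0)
  tries <- 0L
  while (nrow(positions) < nw && tries < 50L) {
    cand <- prior_sampler(nw)
    v <- apply(cand, 1, lp_total)
    ok <- is.finite(v)
    positions <- rbind(positions, cand[ok, , drop = FALSE])
    lps <- c(lps, v[ok])
    tries <- tries + 1L
  }
  if (nrow(positions) < nw) stop("could not initialize ensemble from prior")
  positions <- positions[seq_len(nw), , drop = FALSE]

  # ---- annealing up the beta ladder, pooling elite samples as we go
  pool_x <- NULL; pool_lp <- numeric(0)
  add_pool <- function(x, lp) {
    pool_x <<- rbind(pool_x, x); pool_lp <<- c(pool_lp, lp)
    if (length(pool_lp) > 4L * config$select_pool) {
      keep <- order(pool_lp, decreasing = TRUE)[seq_len(config$select_pool)]
      pool_x <<- pool_x[keep, , drop = FALSE]; pool_lp <<- pool_lp[keep]
    }
  }
  for (beta in config$anneal_betas) {
    run <- kai_run_ensemble(logpost_fn, positions, config$anneal_steps,
                            alpha = config$alpha, beta = beta,
                            thin = max(1L, config$anneal_steps %/% 20L))
    positions <- run$positions
    flat <- matrix(aperm(run$chain, c(2, 1, 3)), ncol = n_dims)
    flat_lp <- as.vector(t(run$chain_log_target)) +
      (1 - beta) * as.vector(t(run$chain_log_lik)) # full-posterior value
    add_pool(flat, flat_lp)
  }

  generation <- 0L
  converged <- FALSE
  best_opt_lp <- -Inf
  run <- NULL
  repeat {
    generation <- generation + 1L

    # ---- selection: top pool, stratified pick, Powell polish
    dup <- duplicated(round(pool_x, 12))
    px <- pool_x[!dup, , drop = FALSE]; plp <- pool_lp[!dup]
    ord <- order(plp, decreasing = TRUE)
    top <- ord[seq_len(min(config$select_pool, length(ord)))]
    k <- min(config$select_k, length(top), nw)
    pick <- unique(c(top[1], top[round(seq(1, length(top), length.out = k))]))
    pick <- pick[seq_len(min(length(pick), nw))]
    opt <- lapply(pick, function(i) {
      kai_local_optimize(lp_total, px[i, ],
                         control = list(maxit = config$powell_maxit,
                                        reltol = 1e-8, step = 0.25,
                                        line_tol = config$powell_line_tol))
    })
    opt_x <- do.call(rbind, lapply(opt, `[[`, "par"))
    opt_lp <- vapply(opt, `[[`, numeric(1), "log_posterior")
    best_opt_lp <- max(best_opt_lp, opt_lp)

    # ---- recombination: allocate walkers ~ posterior^reseed_beta,
    # jitter with N(0, reseed_sd); elitist: best optimum kept exactly
    alloc <- kai_reseed_allocation(opt_lp, nw, config$reseed_beta)
    seeds <- do.call(rbind, lapply(seq_along(alloc), function(i) {
      matrix(rep(opt_x[i, ], alloc[i]), nrow = alloc[i], byrow = TRUE)
    }))
    noise <- matrix(stats::rnorm(nw * n_dims, 0, config$reseed_sd),
                    nw, n_dims)
    i_best <- which.max(opt_lp)
    row_best <- if (i_best == 1L) 1L else sum(alloc[seq_len(i_best - 1L)]) + 1L
    noise[row_best, ] <- 0
    positions <- seeds + noise
    # guard against invalid jittered seeds
    v <- apply(positions, 1, lp_total)
    bad <- !is.finite(v)
    for (i in which(bad)) positions[i, ] <- opt_x[i_best, ] +
      stats::rnorm(n_dims, 0, config$reseed_sd / 10)

    # ---- sampling run
    run <- kai_run_ensemble(logpost_fn, positions, config$sample_steps,
                            alpha = config$alpha, beta = 1,
                            thin = config$thin)
    positions <- run$positions
    flat <- matrix(aperm(run$chain, c(2, 1, 3)), ncol = n_dims)
    add_pool(flat, as.vector(t(run$chain_log_target)))
    best_sampled <- max(run$chain_log_target)

    # ---- termination test
    if (best_sampled <= best_opt_lp + config$improvement_tol) {
      extra <- kai_run_ensemble(logpost_fn, positions, config$extra_steps,
                                alpha = config$alpha, beta = 1,
                                thin = config$thin)
      run$chain <- abind2(run$chain, extra$chain)
      run$chain_log_target <- rbind(run$chain_log_target,
                                    extra$chain_log_target)
      run$positions <- extra$positions
      run$acceptance <- mean(c(run$acceptance, extra$acceptance))
      converged <- TRUE
      break
    }
    if (generation >= config$max_generations) {
      warning("fit budget exhausted before termination; returning best so far")
      break
    }
  }

  keep_steps <- max(1L, config$post_window %/% config$thin)
  n_kept <- dim(run$chain)[1]
  sel <- seq.int(max(1L, n_kept - keep_steps + 1L), n_kept)
  i_best <- arrayInd(which.max(run$chain_log_target),
                     dim(run$chain_log_target))
  best_x <- run$chain[i_best[1], i_best[2], ]
  best_lp <- run$chain_log_target[i_best[1], i_best[2]]
  if (best_opt_lp > best_lp) {
    best_x <- opt_x[which.max(opt_lp), ]
    best_lp <- best_opt_lp
  }
  list(best = best_x, best_log_posterior = best_lp,
       chain = run$chain[sel, , , drop = FALSE],
       chain_log_posterior = run$chain_log_target[sel, , drop = FALSE],
       final_positions = run$positions,
       generations = generation, converged = converged,
       acceptance = run$acceptance)
}

#' Tempered-posterior walker allocation
#'
#' Splits `n_walkers` reseed slots across optimized seeds proportionally
#' to their posterior raised to a temperature exponent,
#' `n_j = n_walkers * p_j^beta / sum_k p_k^beta` (computed stably in log
#' space, rounded with every seed keeping at least one walker). The
#' exponent < 1 deliberately over-allocates to lower-posterior optima so
#' the sampling run keeps exploring secondary maxima.
#'
#' @param log_posteriors Log-posterior values of the optimized seeds.
#' @param n_walkers Total walkers to allocate.
#' @param beta Temperature exponent (default 0.6).
#' @return Integer vector summing to `n_walkers`.
#' @export
kai_reseed_allocation <- function(log_posteriors, n_walkers, beta = 0.6) {
  stopifnot(length(log_posteriors) >= 1L,
            n_walkers >= length(log_posteriors))
  w <- exp(beta * (log_posteriors - max(log_posteriors)))
  alloc <- pmax(1L, as.integer(round(n_walkers * w / sum(w))))
  while (sum(alloc) > n_walkers) {
    i <- which.max(alloc); alloc[i] <- alloc[i] - 1L
  }
  while (sum(alloc) < n_walkers) {
    i <- which.min(alloc); alloc[i] <- alloc[i] + 1L
  }
  alloc
}

# bind two (steps x walkers x dims) arrays along the first margin
abind2 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[2] == db[2], da[3] == db[3])
  out <- array(NA_real_, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}
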