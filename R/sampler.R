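# Affine-invariant ensemble MCMC (Goodman-Weare stretch move), with
# optional likelihood tempering. Updates are sequential over walkers; all
# randomness goes through R's RNG so seeded runs reproduce bit-for-bit.

#' Draw a stretch factor z
#'
#' By default z is drawn from the density g(z) proportional to 1/sqrt(z)
#' on \[1/alpha, alpha\] (the standard Goodman-Weare form, for which the
#' z^(N-1) factor in the acceptance probability is exact). A `"reciprocal"`
#' variant with g(z) proportional to 1/z on the same support is available;
#' the two differ only in how step lengths are distributed.
#'
#' @param n Number of draws.
#' @param alpha Stretch parameter, > 1.
#' @param variant `"sqrt"` (default) or `"reciprocal"`.
#' @return Numeric vector of stretch factors in \[1/alpha, alpha\].
#' @export
kai_stretch_z <- function(n = 1, alpha = 1.1,
                          variant = c("sqrt", "reciprocal")) {
  variant <- match.arg(variant)
  if (alpha <= 1) stop("alpha must exceed 1")
  u <- stats::runif(n)
  if (variant == "sqrt") {
    ((alpha - 1) * u + 1)^2 / alpha
  } else {
    alpha^(2 * u - 1)
  }
}

#' Density of the stretch factor
#' @param z Evaluation points.
#' @inheritParams kai_stretch_z
#' @return Density values (0 outside \[1/alpha, alpha\]).
#' @export
kai_stretch_density <- function(z, alpha = 1.1,
                                variant = c("sqrt", "reciprocal")) {
  variant <- match.arg(variant)
  inside <- z >= 1 / alpha & z <= alpha
  d <- numeric(length(z))
  if (variant == "sqrt") {
    # normalization: integral of z^(-1/2) over [1/a, a] = 2(sqrt(a)-1/sqrt(a))
    d[inside] <- 1 / sqrt(z[inside]) / (2 * (sqrt(alpha) - 1 / sqrt(alpha)))
  } else {
    d[inside] <- 1 / z[inside] / (2 * log(alpha))
  }
  d
}

#' Stretch-move proposal
#'
#' Moves walker `theta_k` along the line through its randomly chosen
#' partner `theta_j`: `proposal = theta_j + z * (theta_k - theta_j)`.
#'
#' @param theta_k Walker being updated (numeric vector).
#' @param theta_j Partner walker.
#' @param alpha Stretch parameter, > 1.
#' @param variant Stretch density variant, see [kai_stretch_z()].
#' @return List with `proposal` and the stretch factor `z`.
#' @export
kai_stretch_move <- function(theta_k, theta_j, alpha = 1.1,
                             variant = c("sqrt", "reciprocal")) {
  if (alpha <= 1) stop("alpha must exceed 1")
  z <- kai_stretch_z(1, alpha, variant)
  list(proposal = theta_j + z * (theta_k - theta_j), z = z)
}

#' Stretch-move acceptance decision
#'
#' Accepts with probability `min(1, z^(N-1) * exp(logpost_new -
#' logpost_old))`, where N is the dimension of the walkers; this makes the
#' ensemble chain reversible with respect to the target.
#'
#' @param z Stretch factor of the proposal.
#' @param n_dims Dimension N of the parameter space.
#' @param logpost_new,logpost_old Log target values.
#' @return Logical; `TRUE` to accept. A non-finite `logpost_new` is always
#'   rejected.
#' @export
kai_stretch_accept <- function(z, n_dims, logpost_new, logpost_old) {
  if (!is.finite(logpost_old)) stop("logpost_old must be finite")
  if (!is.finite(logpost_new)) return(FALSE)
  logq <- (n_dims - 1) * log(z) + logpost_new - logpost_old
  log(stats::runif(1)) < logq
}

#' Run the ensemble sampler
#'
#' Sequentially updates each walker by a stretch move against a partner
#' drawn uniformly from the rest of the ensemble. When `beta < 1` the
#' target is the tempered posterior `beta * log_lik + log_prior`: only the
#' likelihood is flattened, never the prior. In that case `fn` must return
#' a length-2 numeric `c(log_prior, log_lik)`; at `beta = 1` a scalar
#' log-target is also accepted.
#'
#' @param fn Log-target function of one numeric vector; returns a scalar,
#'   or `c(log_prior, log_lik)`.
#' @param positions `n_walkers x n_dims` matrix of starting positions; all
#'   must have finite log-target.
#' @param n_steps Number of ensemble sweeps.
#' @param alpha Stretch parameter.
#' @param beta Likelihood tempering exponent in \[0, 1\].
#' @param thin Keep every `thin`-th sweep in the returned chain.
#' @param variant Stretch density variant.
#' @return List with final `positions`, `log_target` (and `log_lik` when
#'   available) per walker, the thinned `chain` (array steps x walkers x
#'   dims), `chain_log_target`, `chain_log_lik`, and the mean `acceptance`
#'   fraction.
#' @export
kai_run_ensemble <- function(fn, positions, n_steps, alpha = 1.1, beta = 1,
                             thin = 1L, variant = c("sqrt", "reciprocal")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(positions), n_steps >= 1)
  nw <- nrow(positions); nd <- ncol(positions)
  if (nw <= nd) stop("the ensemble needs more walkers than free parameters")
  if (nw < 3L) stop("need at least 3 walkers")
  if (all(apply(positions, 2, function(x) diff(range(x)) == 0))) {
    stop("degenerate ensemble: all walkers identical")
  }
  eval_fn <- function(theta) {
    v <- fn(theta)
    if (length(v) == 2L) c(target = v[[1]] + beta * v[[2]], ll = v[[2]])
    else c(target = v[[1]], ll = NA_real_)
  }
  cur <- t(apply(positions, 1, eval_fn))
  if (any(!is.finite(cur[, "target"]))) {
    stop("all initial walkers must have finite log-target")
  }
  n_keep <- length(seq.int(thin, n_steps, by = thin))
  chain <- array(NA_real_, c(n_keep, nw, nd))
  chain_lt <- matrix(NA_real_, n_keep, nw)
  chain_ll <- matrix(NA_real_, n_keep, nw)
  kept <- 0L
  n_acc <- 0L
  zvals <- kai_stretch_z(n_steps * nw, alpha, variant)
  zi <- 0L
  for (s in seq_len(n_steps)) {
    for (k in seq_len(nw)) {
      j <- sample.int(nw - 1L, 1L)
      if (j >= k) j <- j + 1L
      zi <- zi + 1L
      z <- zvals[zi]
      prop <- positions[j, ] + z * (positions[k, ] - positions[j, ])
      v <- eval_fn(prop)
      if (kai_stretch_accept(z, nd, v[["target"]], cur[k, "target"])) {
        positions[k, ] <- prop
        cur[k, ] <- v
        n_acc <- n_acc + 1L
      }
    }
    if (s %% thin == 0L) {
      kept <- kept + 1L
      chain[kept, , ] <- positions
      chain_lt[kept, ] <- cur[, "target"]
      chain_ll[kept, ] <- cur[, "ll"]
    }
  }
  list(positions = positions, log_target = cur[, "target"],
       log_lik = cur[, "ll"], chain = chain, chain_log_target = chain_lt,
       chain_log_lik = chain_ll, acceptance = n_acc / (n_steps * nw))
}
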