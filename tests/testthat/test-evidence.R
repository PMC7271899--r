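# Tempered-ladder marginal likelihood, Bayes factors, and model variants.

# conjugate 1-D Gaussian: y_i ~ N(mu, s2) with known s2, prior
# mu ~ N(mu0, t2); the log marginal likelihood is available in closed form
conjugate_problem <- function(n = 12, mu_true = 1.2, s2 = 0.5,
                              mu0 = 0, t2 = 4, seed = 8) {
  set.seed(seed)
  y <- stats::rnorm(n, mu_true, sqrt(s2))
  fn <- function(theta) {
    mu <- theta[1]
    c(stats::dnorm(mu, mu0, sqrt(t2), log = TRUE),
      sum(stats::dnorm(y, mu, sqrt(s2), log = TRUE)))
  }
  # closed form: y | model ~ N(mu0 * 1, s2 I + t2 J)
  Sigma <- diag(s2, n) + t2
  lml <- as.numeric(-0.5 * (n * log(2 * pi) +
                              determinant(Sigma)$modulus +
                              t(y - mu0) %*% solve(Sigma) %*% (y - mu0)))
  list(fn = fn, y = y, log_marginal = lml,
       post_mean = (mu0 / t2 + sum(y) / s2) / (1 / t2 + n / s2),
       post_var = 1 / (1 / t2 + n / s2))
}

test_that("ladder estimate matches the conjugate closed form within 3 SE", {
  # the fine (0.01) ladder keeps successive tempered targets overlapping,
  # which controls the finite-sample bias of each free-energy increment;
  # coarse ladders show a visible upward Jensen bias on this problem
  prob <- conjugate_problem()
  set.seed(31)
  pos <- matrix(stats::rnorm(24, prob$post_mean, sqrt(prob$post_var)),
                24, 1)
  cfg <- kai_config("test", evidence_lambda_step = 0.01,
                    evidence_stage_steps = 150, evidence_use_last = 75,
                    alpha = 2)
  est <- kai_log_evidence(prob$fn, pos, cfg, n_boot = 30)
  expect_lt(abs(est$log_evidence - prob$log_marginal),
            3 * max(est$se, 0.02))
  expect_equal(nrow(est$ladder), 100)
  expect_false(any(est$ladder$flagged))
})

test_that("a constant likelihood telescopes exactly and self-comparison gives B = 1", {
  # L == exp(c): every stage average is exp(-dlam * c) exactly, so the
  # product telescopes to c with zero MC error
  cst <- -3.7
  fn <- function(theta) c(-theta[1]^2 / 2, cst)
  set.seed(5)
  pos <- matrix(stats::rnorm(12), 12, 1)
  cfg <- kai_config("test", evidence_lambda_step = 0.25,
                    evidence_stage_steps = 40, evidence_use_last = 20,
                    alpha = 2)
  est <- kai_log_evidence(fn, pos, cfg, n_boot = 10)
  expect_equal(est$log_evidence, cst, tolerance = 1e-10)
  expect_lt(est$se, 1e-10)
  bf <- kai_bayes_factor(est$log_evidence, est$log_evidence)
  expect_equal(bf$bayes_factor, 1)
  expect_false(bf$substantial)
  # a ln-evidence gap of ln(10.4) is a Bayes factor of 10.4
  expect_equal(kai_bayes_factor(log(10.4), 0)$bayes_factor, 10.4)
  expect_true(kai_bayes_factor(log(10.4), 0)$substantial)
})

test_that("ladder telescoping is invariant to splitting an interval", {
  prob <- conjugate_problem(seed = 9)
  run <- function(lams, seed) {
    set.seed(seed)
    pos <- matrix(stats::rnorm(24, prob$post_mean, sqrt(prob$post_var)),
                  24, 1)
    cfg <- kai_config("test", evidence_stage_steps = 250,
                      evidence_use_last = 120, alpha = 2)
    kai_log_evidence(prob$fn, pos, cfg, lambdas = lams)
  }
  coarse <- run(seq(1, 0.2, by = -0.2), 41)
  fine <- run(seq(1, 0.1, by = -0.1), 42)
  joint_se <- sqrt(coarse$se^2 + fine$se^2)
  expect_lt(abs(coarse$log_evidence - fine$log_evidence),
            3 * max(joint_se, 0.02))
})

test_that("estimator precision improves with stage length", {
  # the empirical spread of repeated estimates shrinks when each stage
  # collects more samples (roughly sqrt(2) per doubling)
  prob <- conjugate_problem(seed = 10)
  est_at <- function(steps, seed) {
    set.seed(seed)
    pos <- matrix(stats::rnorm(24, prob$post_mean, sqrt(prob$post_var)),
                  24, 1)
    cfg <- kai_config("test", evidence_lambda_step = 0.1,
                      evidence_stage_steps = steps,
                      evidence_use_last = steps %/% 2, alpha = 2)
    kai_log_evidence(prob$fn, pos, cfg, n_boot = 2)$log_evidence
  }
  short <- vapply(1:8, function(s) est_at(60, s), numeric(1))
  long <- vapply(1:8, function(s) est_at(480, s + 100), numeric(1))
  expect_lt(stats::sd(long), stats::sd(short))
})

test_that("variant construction: free coordinate counts and ties", {
  expect_length(kai_variant("full")$free_delta, 34)
  expect_length(kai_variant("minus_n")$free_delta, 26)
  expect_length(kai_variant("minus_p")$free_delta, 22)
  expect_length(kai_variant("minus_n_p")$free_delta, 20)

  # full round-trips to the unmodified model
  p <- random_params(13)
  v <- kai_variant("full")
  expect_equal(v$expand(p$delta_log10), p$delta_log10)

  # minus_n: every KaiA on/off rate is independent of the nucleotide
  # state, including the detailed-balance-derived ones
  set.seed(2)
  vn <- kai_variant("minus_n")
  fd <- stats::setNames(stats::rnorm(26), vn$free_delta)
  pn <- kai_params(delta_log10 = vn$expand(fd))
  rr <- kai_reaction_rates(pn, 100)
  for (X in c("U", "T", "S", "D")) {
    on_tp <- rate_of(rr, paste0("C_TP_", X), paste0("AC_TP_", X))
    on_dp <- rate_of(rr, paste0("C_DP_", X), paste0("AC_DP_", X))
    off_tp <- rate_of(rr, paste0("AC_TP_", X), paste0("C_TP_", X))
    off_dp <- rate_of(rr, paste0("AC_DP_", X), paste0("C_DP_", X))
    expect_equal(on_tp, on_dp, tolerance = 1e-12)
    expect_equal(off_tp, off_dp, tolerance = 1e-12)
  }

  # minus_p: dissociation constants depend only on the nucleotide state
  vp <- kai_variant("minus_p")
  fdp <- stats::setNames(stats::rnorm(22), vp$free_delta)
  pp <- kai_params(delta_log10 = vp$expand(fdp))
  rrp <- kai_reaction_rates(pp, 100)
  kd_of <- function(X, nuc) {
    rate_of(rrp, paste0("AC_", nuc, "_", X), paste0("C_", nuc, "_", X)) /
      rate_of(rrp, paste0("C_", nuc, "_", X), paste0("AC_", nuc, "_", X))
  }
  for (nuc in c("TP", "DP")) {
    kds <- vapply(c("U", "T", "S", "D"), kd_of, numeric(1), nuc = nuc)
    expect_lt(diff(range(kds)) / mean(kds), 1e-10)
  }

  # minus_n_p: a single on/off pair -- the base rates themselves
  vnp <- kai_variant("minus_n_p")
  fdnp <- stats::setNames(stats::rnorm(20), vnp$free_delta)
  pnp <- kai_params(delta_log10 = vnp$expand(fdnp))
  rrnp <- kai_reaction_rates(pnp, 100)
  ons <- offs <- c()
  for (X in c("U", "T", "S", "D")) for (nuc in c("TP", "DP")) {
    ons <- c(ons, rate_of(rrnp, paste0("C_", nuc, "_", X),
                          paste0("AC_", nuc, "_", X)))
    offs <- c(offs, rate_of(rrnp, paste0("AC_", nuc, "_", X),
                            paste0("C_", nuc, "_", X)))
  }
  expect_equal(unname(ons), rep(pnp$base[["ka"]], 8), tolerance = 1e-12)
  expect_equal(unname(offs), rep(pnp$base[["kb"]], 8), tolerance = 1e-12)

  # every variant still satisfies detailed balance around each cycle
  for (nm in c("minus_n", "minus_p", "minus_n_p")) {
    vv <- kai_variant(nm)
    fdv <- stats::setNames(stats::rnorm(length(vv$free_delta)),
                           vv$free_delta)
    pv <- kai_params(delta_log10 = vv$expand(fdv))
    rrv <- kai_reaction_rates(pv, 100)
    for (cyc in kai_balance_cycles()) {
      nxt <- c(cyc[-1], cyc[1])
      fwd <- prod(vapply(seq_along(cyc), function(i) {
        rate_of(rrv, cyc[i], nxt[i])
      }, numeric(1)))
      rev <- prod(vapply(seq_along(cyc), function(i) {
        rate_of(rrv, nxt[i], cyc[i])
      }, numeric(1)))
      expect_equal(fwd / rev, 1, tolerance = 1e-12)
    }
  }
  expect_error(kai_variant("bogus"))
})

test_that("projection onto a variant preserves the tied-group geometry", {
  p <- kai_default_truth()$params
  for (anchor in c("baseline", "mean")) {
    pn <- kai_variant_project(p, "minus_n", anchor = anchor)
    rr <- kai_reaction_rates(pn, 100)
    # ties hold
    for (X in c("U", "D")) {
      expect_equal(rate_of(rr, paste0("C_TP_", X), paste0("AC_TP_", X)),
                   rate_of(rr, paste0("C_DP_", X), paste0("AC_DP_", X)),
                   tolerance = 1e-12)
    }
  }
  # mean anchoring preserves the geometric-mean U affinity of the truth
  pn <- kai_variant_project(p, "minus_n", anchor = "mean")
  rr <- kai_reaction_rates(pn, 100)
  rr0 <- kai_reaction_rates(p, 100)
  kd <- function(rrx, X, nuc) {
    rate_of(rrx, paste0("AC_", nuc, "_", X), paste0("C_", nuc, "_", X)) /
      rate_of(rrx, paste0("C_", nuc, "_", X), paste0("AC_", nuc, "_", X))
  }
  expect_equal(kd(rr, "U", "TP"),
               sqrt(kd(rr0, "U", "TP") * kd(rr0, "U", "DP")),
               tolerance = 1e-10)
})

test_that("tempered evidence realizes the complexity penalty on nested variants", {
  # reduced-dimension surrogate: data from a model whose two KaiA
  # coordinates are tied; the 2-parameter 'full' surrogate must not beat
  # the 1-parameter tied surrogate by a substantial Bayes factor
  set.seed(77)
  n <- 30
  x <- stats::rnorm(n, 1.5, 0.4) # data from the tied truth (both coords 1.5)
  s2 <- 0.16
  fn_full <- function(th) {
    c(sum(stats::dnorm(th, 0, 3, log = TRUE)),
      sum(stats::dnorm(x[1:15], th[1], sqrt(s2), log = TRUE)) +
        sum(stats::dnorm(x[16:30], th[2], sqrt(s2), log = TRUE)))
  }
  fn_tied <- function(th) {
    c(stats::dnorm(th[1], 0, 3, log = TRUE),
      sum(stats::dnorm(x, th[1], sqrt(s2), log = TRUE)))
  }
  cfg <- kai_config("test", evidence_lambda_step = 0.05,
                    evidence_stage_steps = 250, evidence_use_last = 120,
                    alpha = 2)
  pos_full <- matrix(stats::rnorm(48, mean(x), 0.2), 24, 2)
  ev_full <- kai_log_evidence(fn_full, pos_full, cfg)
  pos_tied <- matrix(stats::rnorm(24, mean(x), 0.15), 24, 1)
  ev_tied <- kai_log_evidence(fn_tied, pos_tied, cfg)
  bf <- kai_bayes_factor(ev_full$log_evidence, ev_tied$log_evidence)
  expect_lt(bf$bayes_factor, 3.2)
})
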