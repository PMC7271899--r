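# Shared test fixtures, all built in code.

# a parameter set with every Delta-k drawn at random (reproducibly)
random_params <- function(seed = 1, spread = 1) {
  set.seed(seed)
  delta <- stats::setNames(stats::rnorm(34, 0, spread), kai_delta_names())
  fr <- as.vector(stats::rgamma(8, c(20, 100, 1, 1, 1, 1, 1, 1)))
  fr <- fr / sum(fr)
  kai_params(
    base = c(kp = 10^stats::rnorm(1, -3.6, 0.3),
             kd = 10^stats::rnorm(1, -3.3, 0.3),
             ka = 0.0279, kb = 0.0663,
             krDP = 10^stats::rnorm(1, -2.7, 0.3),
             kh = 10^stats::rnorm(1, -3.3, 0.3)),
    delta_log10 = delta, sigma2 = 0.01,
    init_frac = stats::setNames(fr[1:7], kai_init_names()))
}

# per-reaction rate lookup from the rate table
rate_of <- function(rr, from, to) {
  i <- which(rr$from == from & rr$to == to)
  stopifnot(length(i) >= 1L)
  sum(rr$rate[i])
}

# tiny two-condition dataset generated from the default truth; used by the
# reduced-dimension posterior in the recovery and sampler tests
reduced_dataset <- function(noise_sd = 0.5, seed = 1) {
  design <- kai_design(kaiA_levels = c(0.75, 3.00), pctATP_levels = 25,
                       phos_times = c(0, 4, 8, 12.25, 24),
                       dephos_times = seq(0, 16, by = 4),
                       noise_sd = noise_sd)
  truth <- kai_default_truth(noise_sd = noise_sd)
  kai_generate(design, truth, seed = seed)
}

# log-posterior over a small set of free coordinates, everything else
# pinned at the default truth; returns c(log_prior, log_lik)
reduced_logpost <- function(dataset, free = c("log10_kh", "dkb_U_DP")) {
  truth <- kai_default_truth()$params
  spec <- kai_prior_spec()
  function(theta) {
    stopifnot(length(theta) == length(free))
    names(theta) <- free
    base <- truth$base
    delta <- truth$delta_log10
    for (nm in free) {
      if (startsWith(nm, "log10_")) {
        base[sub("log10_", "", nm)] <- 10^theta[[nm]]
      } else {
        delta[nm] <- theta[[nm]]
      }
    }
    p <- kai_params(base = base, delta_log10 = delta,
                    sigma2 = truth$sigma2, init_frac = truth$init_frac)
    lp <- kai_log_prior(p, spec)
    if (!is.finite(lp)) return(c(lp, -Inf))
    pr <- kai_predict(p, dataset)
    if (is.null(pr)) return(c(lp, -Inf))
    ll <- kai_log_likelihood_timeseries(p, dataset, pr) +
      kai_log_likelihood_hydrolysis(p, dataset, pr)
    c(lp, ll)
  }
}
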