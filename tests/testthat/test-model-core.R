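# State space, rate construction, detailed balance, and the ODE forward
# model.

test_that("state enumeration is complete and uniquely labeled", {
  st <- kai_states()
  expect_equal(nrow(st), 16L)
  expect_equal(anyDuplicated(st$label), 0L)
  expect_equal(sum(!st$kaiA_bound), 8L)
  # the dephosphorylation endpoint is a single state
  endpoint <- st[st$phos == "U" & st$nuc == "DP" & !st$kaiA_bound, ]
  expect_equal(nrow(endpoint), 1L)
  expect_equal(endpoint$label, "C_DP_U")
  # index helper agrees with the enumeration
  for (i in seq_len(16L)) {
    expect_equal(kai_state_index(as.character(st$phos[i]),
                                 as.character(st$nuc[i]),
                                 st$kaiA_bound[i]), i)
  }
})

test_that("parameter bookkeeping: 6 + 34 + 1 + 7 free scalars, 4 derived", {
  expect_length(kai_base_names(), 6L)
  expect_length(kai_delta_names(), 34L)
  expect_length(kai_derived_delta_names(), 4L)
  p <- kai_params()
  expect_length(kai_pack(p), 48L)
  rt <- kai_unpack(kai_pack(p))
  expect_equal(rt$base, p$base, tolerance = 1e-12)
  expect_equal(rt$delta_log10, p$delta_log10)
  expect_equal(rt$init_frac, p$init_frac)
})

test_that("exchange rate is linear in %ATP with zero reverse rate", {
  expect_equal(kai_exchange_rate(0.1, 100), 0.1)
  expect_equal(kai_exchange_rate(0.1, 50), 0.05)
  expect_lt(kai_exchange_rate(5, 1e-6), 1e-6) # vanishes as %ATP -> 0
  expect_error(kai_exchange_rate(-0.1, 50), "non-negative")
  expect_error(kai_exchange_rate(0.1, 0), "0, 100")
})

test_that("detailed balance: symmetric case, cycle products, locality", {
  zero <- stats::setNames(numeric(34), kai_delta_names())
  expect_equal(unname(kai_detailed_balance(zero)), rep(0, 4))
  expect_error(kai_detailed_balance(zero[-1]), "34")
  expect_error(kai_detailed_balance(replace(zero, 3, NaN)), "finite")

  # independent check: multiply actual per-reaction rates around each
  # cycle; forward/reverse product ratio must be 1 (KaiA binding is
  # second-order in both directions of the cycle, so the free-KaiA factor
  # cancels and the rate constants alone must balance)
  for (seed in 1:25) {
    p <- random_params(seed)
    rr <- kai_reaction_rates(p, pct_ATP = 100)
    for (cyc in kai_balance_cycles()) {
      fwd <- prod(vapply(seq_along(cyc), function(i) {
        rate_of(rr, cyc[i], cyc[ifelse(i == length(cyc), 1, i + 1)])
      }, numeric(1)))
      rev <- prod(vapply(seq_along(cyc), function(i) {
        rate_of(rr, cyc[ifelse(i == length(cyc), 1, i + 1)], cyc[i])
      }, numeric(1)))
      expect_equal(fwd / rev, 1, tolerance = 1e-12)
    }
  }

  # perturbing one free factor of a cycle changes exactly one derived one
  base <- kai_detailed_balance(zero)
  d2 <- replace(zero, which(names(zero) == "dkpA_UT"), 0.7)
  changed <- which(abs(kai_detailed_balance(d2) - base) > 1e-14)
  expect_equal(names(base)[changed], "dka_T_DP")
})

test_that("reaction network structure follows the catalytic rules", {
  p <- random_params(3)
  rr <- kai_reaction_rates(p, pct_ATP = 100)
  st <- kai_states()
  phos_of <- function(lab) st$phos[match(lab, st$label)]
  nuc_of <- function(lab) st$nuc[match(lab, st$label)]
  bound_of <- function(lab) st$kaiA_bound[match(lab, st$label)]
  order_rank <- c(U = 1, T = 2, S = 2, D = 3)
  tr <- rr[rr$type == "transfer", ]
  up <- order_rank[as.character(phos_of(tr$to))] >
    order_rank[as.character(phos_of(tr$from))]
  # phosphorylation only from ATP-bound states, dephosphorylation only
  # from ADP-bound states; transfer flips the nucleotide
  expect_true(all(nuc_of(tr$from[up]) == "TP"))
  expect_true(all(nuc_of(tr$from[!up]) == "DP"))
  expect_true(all(nuc_of(tr$from) != nuc_of(tr$to)))
  ex <- rr[rr$type == "exchange", ]
  expect_true(all(bound_of(ex$from))) # no KaiA-free exchange
  expect_true(all(nuc_of(ex$from) == "DP")) # no exchange on ATP states
  hy <- rr[rr$type == "hydrolysis", ]
  expect_true(all(nuc_of(hy$from) == "TP" & nuc_of(hy$to) == "DP"))
  # multiplicative scheme: off-rate for the KaiA-bound ATP T state
  expect_equal(rate_of(rr, "AC_TP_T", "C_TP_T"),
               p$base[["kb"]] * 10^p$delta_log10[["dkb_T_TP"]])
})

test_that("mass is conserved and KaiA stays non-negative over 48 h", {
  for (seed in c(2, 5, 11)) {
    p <- random_params(seed, spread = 0.5)
    cond <- kai_condition(kaiA_uM = 1.5, pct_ATP = 50, duration_h = 48)
    tr <- kai_simulate(p, cond, t_grid = seq(0, 48, by = 2))
    expect_false(is.null(tr))
    expect_lt(max(abs(rowSums(tr$conc) - cond$kaiC_uM)), 1e-6)
    expect_gt(min(tr$kaiA_free), -1e-9)
    expect_gt(min(tr$conc), -1e-9)
  }
})

test_that("without KaiA activity the system collapses to the ADP-bound U state", {
  p <- kai_default_truth()$params
  p$base["ka"] <- 0
  p <- kai_params(base = p$base, delta_log10 = p$delta_log10,
                  sigma2 = p$sigma2, init_frac = p$init_frac)
  y0 <- stats::setNames(numeric(16), kai_states()$label)
  y0["C_TP_D"] <- 3.5
  tr <- kai_simulate(p, kai_condition(0, 100, duration_h = 96),
                     t_grid = c(0, 96), y0 = y0)
  frac_CDPU <- tr$conc[2, "C_DP_U"] / sum(tr$conc[2, ])
  expect_gt(frac_CDPU, 0.99)
})

test_that("%ATP has no effect when KaiA is absent", {
  p <- random_params(7, spread = 0.5)
  g <- seq(0, 24, by = 4)
  tr10 <- kai_simulate(p, kai_condition(0, 10, duration_h = 24), t_grid = g)
  tr100 <- kai_simulate(p, kai_condition(0, 100, duration_h = 24), t_grid = g)
  expect_equal(tr10$conc, tr100$conc, tolerance = 1e-8)
})

test_that("4-state U-only subnetwork matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  # KaiA clamped to excess so binding is pseudo-first-order: the U-column
  # dynamics (C_TP_U, C_DP_U, AC_TP_U, AC_DP_U) are linear when
  # phosphotransfer out of U is switched off
  p <- kai_default_truth()$params
  delta <- p$delta_log10
  base <- p$base
  base[c("kp", "kd")] <- 0 # confine mass to the U phosphoform
  p <- kai_params(base = base, delta_log10 = delta, sigma2 = p$sigma2,
                  init_frac = p$init_frac)
  A_clamp <- 500 # uM dimer; KaiC totals ~1e-6 uM so the dent is ~1e-9
  labs <- c("C_TP_U", "C_DP_U", "AC_TP_U", "AC_DP_U")
  rr <- kai_reaction_rates(p, pct_ATP = 100)
  G <- matrix(0, 4, 4, dimnames = list(labs, labs))
  for (i in seq_len(nrow(rr))) {
    if (!(rr$from[i] %in% labs) || !(rr$to[i] %in% labs)) next
    k <- rr$rate[i] * if (rr$order[i] == 2L) A_clamp else 1
    G[rr$to[i], rr$from[i]] <- G[rr$to[i], rr$from[i]] + k
    G[rr$from[i], rr$from[i]] <- G[rr$from[i], rr$from[i]] - k
  }
  y0 <- c(2, 1.2, 0.2, 0.1) * 1e-6
  t_h <- c(0.5, 2, 6)
  cond <- kai_condition(kaiA_uM = 2 * A_clamp, pct_ATP = 100,
                       kaiC_uM = sum(y0), duration_h = max(t_h))
  y0full <- stats::setNames(numeric(16), kai_states()$label)
  y0full[labs] <- y0
  tr <- kai_simulate(p, cond, t_grid = c(0, t_h), y0 = y0full,
                     rtol = 1e-10, atol = 1e-18)
  for (j in seq_along(t_h)) {
    expm_sol <- as.vector(Matrix::expm(G * 3600 * t_h[j]) %*% y0)
    expect_equal(unname(tr$conc[j + 1, labs]), expm_sol, tolerance = 1e-8)
  }
})

test_that("two-stage dephosphorylation protocol follows the pull-down rules", {
  p <- kai_default_truth()$params
  tr <- kai_simulate_dephosphorylation(p, t_grid = seq(0, 48, by = 4))
  expect_false(is.null(tr))
  st <- kai_states()
  # stage-2 total equals stage-1 total minus the removed KaiA-bound states
  cond1 <- kai_condition(1.3, 100, kaiC_uM = 3.4, duration_h = 20)
  y0 <- stats::setNames(numeric(16), st$label)
  y0["C_TP_U"] <- 3.4
  tr1 <- kai_simulate(p, cond1, t_grid = c(0, 20), y0 = y0)
  bound_at_20 <- sum(tr1$conc[2, st$kaiA_bound])
  expect_equal(tr$condition$kaiC_uM, 3.4 - bound_at_20, tolerance = 1e-6)
  # no KaiA-bound KaiC at the stage-2 start
  expect_equal(max(tr$conc[1, st$kaiA_bound]), 0)
  # long-time limit: essentially all U
  ph <- kai_observables(tr)$phosphoforms
  expect_gt(ph$pct_U[nrow(ph)], 95)
})

test_that("observables: percentages, %CP identity, ADP bookkeeping", {
  p <- kai_default_truth()$params
  tr <- kai_simulate(p, kai_condition(1.5, 100), t_grid = seq(0, 24, 2))
  ob <- kai_observables(tr)
  ph <- ob$phosphoforms
  expect_equal(ph$pct_U + ph$pct_T + ph$pct_S + ph$pct_D,
               rep(100, nrow(ph)), tolerance = 1e-9)
  expect_equal(ph$pct_CP, ph$pct_T + ph$pct_S + ph$pct_D)
  expect_gt(ob$ADP_produced_uM, 0)

  # all mass in C_DP_U reads out as pure U, and with no hydrolysis or
  # phosphotransfer from an all-ATP start no ADP is produced
  y0 <- stats::setNames(numeric(16), kai_states()$label)
  y0["C_DP_U"] <- 3.5
  tr2 <- kai_simulate(p, kai_condition(0, 100, duration_h = 1),
                      t_grid = c(0, 1), y0 = y0)
  ph2 <- kai_observables(tr2)$phosphoforms
  expect_equal(ph2$pct_U[1], 100)
  base0 <- p$base
  base0[c("kh", "kp", "kd")] <- 0
  p0 <- kai_params(base = base0, delta_log10 = p$delta_log10,
                   sigma2 = p$sigma2, init_frac = p$init_frac)
  y0 <- stats::setNames(numeric(16), kai_states()$label)
  y0["C_TP_U"] <- 3.5
  tr3 <- kai_simulate(p0, kai_condition(1.5, 100, duration_h = 12),
                      t_grid = c(0, 12), y0 = y0)
  expect_equal(kai_observables(tr3)$ADP_produced_uM, 0, tolerance = 1e-9)
})

test_that("steady-state %CP responds monotonically to the exchange rate", {
  # at 100% ATP and saturating KaiA, faster ADP release can only help
  # phosphorylation
  cps <- vapply(c(5e-4, 2e-3, 8e-3), function(kr) {
    p <- kai_default_truth()$params
    base <- p$base; base["krDP"] <- kr
    p <- kai_params(base = base, delta_log10 = p$delta_log10,
                    sigma2 = p$sigma2, init_frac = p$init_frac)
    tr <- kai_simulate(p, kai_condition(6, 100, duration_h = 48),
                       t_grid = c(0, 48))
    ph <- kai_observables(tr)$phosphoforms
    ph$pct_CP[2]
  }, numeric(1))
  expect_true(all(diff(cps) > -1e-6))
})

test_that("parameter sets and trajectories serialize and round-trip", {
  p <- random_params(9)
  f <- tempfile(fileext = ".json")
  kai_params_to_json(p, f)
  p2 <- kai_params_from_json(f)
  expect_equal(p2$base, p$base, tolerance = 1e-12)
  expect_equal(p2$delta_log10, p$delta_log10, tolerance = 1e-12)
  expect_equal(p2$derived_delta_log10, p$derived_delta_log10,
               tolerance = 1e-12)
  tr <- kai_simulate(kai_default_truth()$params, kai_condition(1.5, 100),
                     t_grid = c(0, 6, 12))
  csv <- tempfile(fileext = ".csv")
  kai_write_trajectory(tr, csv)
  long <- utils::read.csv(csv)
  expect_equal(nrow(long), 3 * 16)
  expect_true(file.exists(paste0(csv, ".manifest.json")))
  unlink(c(f, csv, paste0(csv, ".manifest.json")))
})
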