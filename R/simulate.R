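# Forward model: mass-action ODEs over the 16 KaiC states. Internal rates
# are in s^-1 (ka in s^-1 uM^-1); time I/O is in hours, with the 3600
# conversion applied once at the integrator boundary. Free KaiA (dimer) is
# handled algebraically by conservation rather than as an ODE variable.

#' Define a simulation condition
#'
#' @param kaiA_uM Total KaiA concentration in monomer units (uM). KaiA
#'   functions as a dimer, so the concentration entering the rate laws is
#'   `kaiA_uM / 2`.
#' @param pct_ATP Solution \%ATP, `100 * [ATP] / ([ATP] + [ADP])`, in
#'   (0, 100]. The total nucleotide pool is treated as constant.
#' @param kaiC_uM Total KaiC concentration (uM).
#' @param duration_h Duration of the simulated reaction (hours).
#' @param protocol `"phosphorylation"` (KaiA added at t = 0 to KaiA-free
#'   KaiC) or `"dephosphorylation_two_stage"` (phosphorylate first, then
#'   remove KaiA by pull-down; see [kai_simulate_dephosphorylation()]).
#' @return A `kai_condition` list.
#' @export
kai_condition <- function(kaiA_uM, pct_ATP = 100, kaiC_uM = 3.5,
                          duration_h = 24,
                          protocol = c("phosphorylation",
                                       "dephosphorylation_two_stage")) {
  protocol <- match.arg(protocol)
  if (!is.finite(pct_ATP) || pct_ATP <= 0 || pct_ATP > 100) {
    stop("pct_ATP must lie in (0, 100]")
  }
  if (kaiA_uM < 0 || kaiC_uM <= 0) stop("concentrations must be non-negative")
  structure(list(kaiA_uM = kaiA_uM, pct_ATP = pct_ATP, kaiC_uM = kaiC_uM,
                 duration_h = duration_h, protocol = protocol),
            class = "kai_condition")
}

#' Effective nucleotide exchange rate
#'
#' KaiA-catalyzed replacement of KaiC-bound ADP by solution ATP proceeds at
#' `krDP * [ATP]/([ATP]+[ADP])`: the ADP release rate scaled by the chance
#' that the transiently empty pocket rebinds ATP rather than ADP (equal
#' nucleotide on-rates). The reverse exchange rate is identically zero
#' because ATP release is taken to be negligible.
#'
#' @param krDP_effective ADP release rate constant, s^-1 (base rate times
#'   any state-dependence factor).
#' @param pct_ATP Solution \%ATP in (0, 100].
#' @return Forward exchange rate constant kTPA in s^-1.
#' @examples
#' kai_exchange_rate(0.1, 50)  # 0.05
#' @export
kai_exchange_rate <- function(krDP_effective, pct_ATP) {
  if (any(krDP_effective < 0)) stop("exchange rate must be non-negative")
  if (any(pct_ATP <= 0 | pct_ATP > 100)) stop("pct_ATP must lie in (0, 100]")
  krDP_effective * pct_ATP / 100
}

# effective per-reaction rate constant: base * 10^(log10 Delta-k)
.dk <- function(params, name) {
  d <- params$delta_log10
  if (name %in% names(d)) return(10^unname(d[name]))
  dd <- params$derived_delta_log10
  if (name %in% names(dd)) return(10^unname(dd[name]))
  1 # baseline reaction: no listed factor
}

#' Per-reaction rate table
#'
#' Expands the multiplicative parameterization into one row per reaction
#' arrow of the network: phosphotransfer (TP state phosphorylates, DP state
#' dephosphorylates, with and without KaiA), irreversible hydrolysis
#' (TP -> DP + Pi), KaiA binding/unbinding, and nucleotide exchange
#' (KaiA-bound DP states only). Rates are s^-1 except KaiA binding
#' (s^-1 uM^-1, to be multiplied by free KaiA dimer concentration).
#'
#' @param params A `kai_params` object (detailed balance already applied at
#'   construction).
#' @param pct_ATP Solution \%ATP used to scale the exchange rates.
#' @return A data frame with columns `from`, `to` (state labels), `type`
#'   (`transfer`, `hydrolysis`, `bind`, `unbind`, `exchange`), `rate`, and
#'   `order` (1 or 2).
#' @export
kai_reaction_rates <- function(params, pct_ATP = 100) {
  stopifnot(inherits(params, "kai_params"))
  b <- params$base
  rows <- list()
  add <- function(from, to, type, rate, order = 1L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      from = from, to = to, type = type, rate = rate, order = order,
      stringsAsFactors = FALSE)
  }
  tp <- kai_transfer_pairs()
  for (i in seq_len(nrow(tp))) {
    X <- tp$from[i]; Y <- tp$to[i]
    # without KaiA; U<->T is the anchored pair (Delta-k = 1)
    fwd <- if (X == "U" && Y == "T") 1 else .dk(params, paste0("dkp_", X, Y))
    rev <- if (X == "U" && Y == "T") 1 else .dk(params, paste0("dkd_", Y, X))
    add(paste0("C_TP_", X), paste0("C_DP_", Y), "transfer", b["kp"] * fwd)
    add(paste0("C_DP_", Y), paste0("C_TP_", X), "transfer", b["kd"] * rev)
    # with KaiA bound
    add(paste0("AC_TP_", X), paste0("AC_DP_", Y), "transfer",
        b["kp"] * .dk(params, paste0("dkpA_", X, Y)))
    add(paste0("AC_DP_", Y), paste0("AC_TP_", X), "transfer",
        b["kd"] * .dk(params, paste0("dkdA_", Y, X)))
  }
  for (X in c("U", "T", "S", "D")) {
    hfree <- if (X == "U") 1 else .dk(params, paste0("dkh_", X))
    add(paste0("C_TP_", X), paste0("C_DP_", X), "hydrolysis", b["kh"] * hfree)
    add(paste0("AC_TP_", X), paste0("AC_DP_", X), "hydrolysis",
        b["kh"] * .dk(params, paste0("dkhA_", X)))
    for (nuc in c("TP", "DP")) {
      dka <- if (X == "U" && nuc == "TP") 1 else
        .dk(params, paste0("dka_", X, "_", nuc))
      dkb <- if (X == "U" && nuc == "TP") 1 else
        .dk(params, paste0("dkb_", X, "_", nuc))
      add(paste0("C_", nuc, "_", X), paste0("AC_", nuc, "_", X), "bind",
          b["ka"] * dka, order = 2L)
      add(paste0("AC_", nuc, "_", X), paste0("C_", nuc, "_", X), "unbind",
          b["kb"] * dkb)
    }
    dx <- if (X == "U") 1 else .dk(params, paste0("dkTPA_", X))
    add(paste0("AC_DP_", X), paste0("AC_TP_", X), "exchange",
        kai_exchange_rate(b["krDP"] * dx, pct_ATP))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Precompute the linear operators for the ODE right-hand side:
#   dx/dt = 3600 * (M0 x + A_free * Mb x),  dPi/dt = 3600 * (h . x)
# M0 collects all first-order reactions, Mb the bilinear KaiA binding, and
# h the hydrolysis rate constants (Pi production). Built by direct index
# arithmetic on the fixed enumeration -- this sits on the hot path of
# every posterior evaluation (kai_reaction_rates is the readable version
# of the same information and is cross-checked against this in the tests).
kai_rate_matrices <- function(params, pct_ATP = 100) {
  b <- params$base
  # one exponentiation pass for all factors; .dk then reads this table
  dk_all <- 10^c(params$delta_log10, params$derived_delta_log10)
  .dk <- function(params, name) {
    v <- dk_all[name]
    if (is.na(v)) 1 else unname(v)
  }
  M0 <- matrix(0, 16, 16)
  Mb <- matrix(0, 16, 16)
  h <- numeric(16)
  idx <- function(phos, nuc, bound) {
    (match(phos, c("U", "T", "S", "D")) - 1L) * 2L +
      match(nuc, c("TP", "DP")) + if (bound) 8L else 0L
  }
  add1 <- function(f, t, k, hyd = FALSE) {
    M0[f, f] <<- M0[f, f] - k
    M0[t, f] <<- M0[t, f] + k
    if (hyd) h[f] <<- h[f] + k
  }
  tp <- kai_transfer_pairs()
  for (i in seq_len(nrow(tp))) {
    X <- tp$from[i]; Y <- tp$to[i]
    anchored <- X == "U" && Y == "T"
    fwd <- if (anchored) 1 else .dk(params, paste0("dkp_", X, Y))
    rev <- if (anchored) 1 else .dk(params, paste0("dkd_", Y, X))
    add1(idx(X, "TP", FALSE), idx(Y, "DP", FALSE), b[["kp"]] * fwd)
    add1(idx(Y, "DP", FALSE), idx(X, "TP", FALSE), b[["kd"]] * rev)
    add1(idx(X, "TP", TRUE), idx(Y, "DP", TRUE),
         b[["kp"]] * .dk(params, paste0("dkpA_", X, Y)))
    add1(idx(Y, "DP", TRUE), idx(X, "TP", TRUE),
         b[["kd"]] * .dk(params, paste0("dkdA_", Y, X)))
  }
  for (X in c("U", "T", "S", "D")) {
    hfree <- if (X == "U") 1 else .dk(params, paste0("dkh_", X))
    add1(idx(X, "TP", FALSE), idx(X, "DP", FALSE), b[["kh"]] * hfree,
         hyd = TRUE)
    add1(idx(X, "TP", TRUE), idx(X, "DP", TRUE),
         b[["kh"]] * .dk(params, paste0("dkhA_", X)), hyd = TRUE)
    for (nuc in c("TP", "DP")) {
      baseline <- X == "U" && nuc == "TP"
      dka <- if (baseline) 1 else .dk(params, paste0("dka_", X, "_", nuc))
      dkb <- if (baseline) 1 else .dk(params, paste0("dkb_", X, "_", nuc))
      f <- idx(X, nuc, FALSE); t <- idx(X, nuc, TRUE)
      kon <- b[["ka"]] * dka
      Mb[f, f] <- Mb[f, f] - kon
      Mb[t, f] <- Mb[t, f] + kon
      add1(t, f, b[["kb"]] * dkb)
    }
    dx <- if (X == "U") 1 else .dk(params, paste0("dkTPA_", X))
    add1(idx(X, "DP", TRUE), idx(X, "TP", TRUE),
         kai_exchange_rate(b[["krDP"]] * dx, pct_ATP))
  }
  list(M0 = M0, Mb = Mb, h = h, bound_idx = 9:16)
}

#' Integrate the kinetic model
#'
#' Solves the stiff mass-action ODE system with a BDF method (deSolve,
#' rtol 1e-6, atol 1e-9 uM). Free KaiA is computed algebraically as
#' total dimer minus the sum of KaiA-bound states, which conserves KaiA
#' exactly. Cumulative inorganic-phosphate production is integrated as an
#' auxiliary state.
#'
#' @param params A `kai_params` object.
#' @param condition A `kai_condition` (its `protocol` is ignored here; the
#'   initial state is the free-KaiC initial fractions unless `y0` is
#'   given).
#' @param t_grid Output time grid in hours; defaults to 0.1 h resolution
#'   over the condition duration.
#' @param y0 Optional length-16 initial state vector (uM) overriding the
#'   default (init fractions times total KaiC on the 8 KaiA-free states,
#'   zero on the KaiA-bound states).
#' @param rtol,atol Integrator tolerances (defaults 1e-6 and 1e-9 uM).
#' @return A `kai_trajectory`: list with `time_h`, the 16-column
#'   concentration matrix `conc` (uM, columns named by state label),
#'   `cumulative_Pi` (uM), `kaiA_free` (dimer, uM) and the condition.
#'   `NULL` on integrator failure (callers treat this as log-posterior
#'   -Inf).
#' @export
kai_simulate <- function(params, condition, t_grid = NULL, y0 = NULL,
                         rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(params, "kai_params"), inherits(condition, "kai_condition"))
  if (is.null(t_grid)) t_grid <- seq(0, condition$duration_h, by = 0.1)
  mats <- kai_rate_matrices(params, condition$pct_ATP)
  A_tot <- condition$kaiA_uM / 2 # dimer
  if (is.null(y0)) {
    fr <- params$init_frac
    y0 <- stats::setNames(numeric(16), kai_states()$label)
    y0[names(fr)] <- fr * condition$kaiC_uM
    y0["C_DP_D"] <- max(0, 1 - sum(fr)) * condition$kaiC_uM
  } else {
    stopifnot(length(y0) == 16L)
  }
  # compiled derivative (src/kai_model.c); the KaiA-bound states are the
  # last 8 of the enumeration, which the C code relies on
  parms <- c(A_tot, as.vector(mats$M0), as.vector(mats$Mb), mats$h)
  sol <- try(deSolve::ode(y = c(unname(y0), 0), times = t_grid,
                          func = "kai_deriv", parms = parms,
                          dllname = "kaikinetics", initfunc = "kai_init",
                          method = "bdf", rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(t_grid) ||
      any(!is.finite(sol))) {
    return(NULL)
  }
  conc <- sol[, 2:17, drop = FALSE]
  colnames(conc) <- kai_states()$label
  structure(list(
    time_h = sol[, 1], conc = conc,
    cumulative_Pi = sol[, 18],
    kaiA_free = A_tot - rowSums(conc[, mats$bound_idx, drop = FALSE]),
    condition = condition), class = "kai_trajectory")
}

#' Simulate the two-stage dephosphorylation protocol
#'
#' Mimics the pull-down experiment: stage 1 phosphorylates 3.4 uM KaiC
#' (all in the ATP-bound U state) with 1.3 uM KaiA (monomer) at 100\% ATP
#' for 20 h; stage 2 then removes all free KaiA and all KaiA-bound KaiC
#' states and follows autodephosphorylation of what remains. The returned
#' trajectory is stage 2 only; because KaiA is absent there is no
#' nucleotide exchange, so the stage-2 kinetics are independent of
#' solution \%ATP.
#'
#' @param params A `kai_params` object.
#' @param t_grid Stage-2 output times in hours (default 0..20 h).
#' @param stage1_kaiC_uM,stage1_kaiA_uM,stage1_duration_h Stage-1 protocol
#'   constants.
#' @return A `kai_trajectory` for stage 2 (its condition records the
#'   reduced KaiC total), or `NULL` on integrator failure.
#' @export
kai_simulate_dephosphorylation <- function(params,
                                           t_grid = seq(0, 20, by = 0.1),
                                           stage1_kaiC_uM = 3.4,
                                           stage1_kaiA_uM = 1.3,
                                           stage1_duration_h = 20) {
  cond1 <- kai_condition(kaiA_uM = stage1_kaiA_uM, pct_ATP = 100,
                         kaiC_uM = stage1_kaiC_uM,
                         duration_h = stage1_duration_h)
  y0 <- stats::setNames(numeric(16), kai_states()$label)
  y0["C_TP_U"] <- stage1_kaiC_uM
  tr1 <- kai_simulate(params, cond1,
                      t_grid = c(0, stage1_duration_h), y0 = y0)
  if (is.null(tr1)) return(NULL)
  y1 <- tr1$conc[nrow(tr1$conc), ]
  y1[kai_states()$kaiA_bound] <- 0 # pull-down removes KaiA-bound KaiC
  kaiC2 <- sum(y1)
  cond2 <- kai_condition(kaiA_uM = 0, pct_ATP = 100, kaiC_uM = kaiC2,
                         duration_h = max(t_grid),
                         protocol = "dephosphorylation_two_stage")
  kai_simulate(params, cond2, t_grid = t_grid, y0 = y1)
}

#' Observables of a trajectory
#'
#' Reduces the 16 state time series to the measured quantities: percent of
#' total KaiC in each phosphoform (summing ATP/ADP-bound and KaiA-bound
#' states), total percent phosphorylation `pct_CP = pct_T + pct_S + pct_D`,
#' and the ADP produced over the first `adp_window_h` hours (cumulative Pi
#' production plus all ADP-bound KaiC at the window end, uM).
#'
#' Concentrations in `[-atol, 0)` are clamped to zero for observable
#' computation only.
#'
#' @param traj A `kai_trajectory`.
#' @param adp_window_h Window for the ADP-production observable (hours).
#' @return A list with data frame `phosphoforms` (columns `time_h`,
#'   `pct_U`, `pct_T`, `pct_S`, `pct_D`, `pct_CP`) and scalar
#'   `ADP_produced_uM` (NA when the trajectory does not cover the window).
#' @export
kai_observables <- function(traj, adp_window_h = 12) {
  stopifnot(inherits(traj, "kai_trajectory"))
  st <- kai_states()
  conc <- pmax(traj$conc, 0)
  tot <- rowSums(conc)
  pct <- sapply(c("U", "T", "S", "D"), function(p) {
    100 * rowSums(conc[, st$phos == p, drop = FALSE]) / tot
  })
  ph <- data.frame(time_h = traj$time_h, pct_U = pct[, "U"],
                   pct_T = pct[, "T"], pct_S = pct[, "S"],
                   pct_D = pct[, "D"])
  ph$pct_CP <- ph$pct_T + ph$pct_S + ph$pct_D
  adp <- NA_real_
  if (max(traj$time_h) >= adp_window_h) {
    i <- which.min(abs(traj$time_h - adp_window_h))
    adp <- traj$cumulative_Pi[i] +
      sum(conc[i, st$nuc == "DP", drop = FALSE])
  }
  list(phosphoforms = ph, ADP_produced_uM = adp)
}

#' Write a trajectory as tidy CSV
#'
#' Long format: one row per (time, state) with columns `time_h`, `state`,
#' `conc_uM`; a run-manifest JSON with the simulation condition is written
#' alongside.
#'
#' @param traj A `kai_trajectory`.
#' @param path CSV output path; the manifest goes to `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
kai_write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "kai_trajectory"))
  long <- data.frame(
    time_h = rep(traj$time_h, times = ncol(traj$conc)),
    state = rep(colnames(traj$conc), each = nrow(traj$conc)),
    conc_uM = as.vector(traj$conc))
  utils::write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(unclass(traj$condition),
                       paste0(path, ".manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
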