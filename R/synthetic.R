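# Synthetic-data generation: datasets with the exact statistical structure
# the likelihood assumes (forward-model trajectories plus i.i.d. Gaussian
# noise with one global standard deviation), over the same condition
# design as the fitting dataset: 6 KaiA levels x 3 %ATP levels x 8
# phosphorylation time points, plus a 21-point dephosphorylation series
# and the hydrolysis bound.

#' Synthetic experimental design
#'
#' @param kaiA_levels KaiA concentrations (monomer, uM).
#' @param pctATP_levels \%ATP conditions.
#' @param phos_times Phosphorylation sampling times (hours); the default
#'   8 points include the 12.25 h near-steady-state time.
#' @param dephos_times Dephosphorylation sampling times (hours; 21 points
#'   over 0-20 h by default).
#' @param kaiC_uM Total KaiC (uM).
#' @param noise_sd Gaussian noise standard deviation, percentage points.
#' @return A `kai_design` list.
#' @export
kai_design <- function(kaiA_levels = c(0.375, 0.75, 1.50, 3.00, 4.50, 6.00),
                       pctATP_levels = c(10, 25, 100),
                       phos_times = c(0, 1, 2, 4, 8, 12.25, 18, 24),
                       dephos_times = seq(0, 20, length.out = 21),
                       kaiC_uM = 3.5,
                       noise_sd = 2) {
  stopifnot(all(kaiA_levels > 0), all(pctATP_levels > 0),
            all(pctATP_levels <= 100), noise_sd >= 0)
  structure(list(kaiA_levels = kaiA_levels, pctATP_levels = pctATP_levels,
                 phos_times = phos_times, dephos_times = dephos_times,
                 kaiC_uM = kaiC_uM, noise_sd = noise_sd),
            class = "kai_design")
}

#' Ground-truth parameter set for synthetic data
#'
#' A documented parameter set built around the substrate-competition
#' mechanism: the KaiA on/off base rates sit at their measured values
#' (ka = 0.0279 s^-1 uM^-1, kb = 0.0663 s^-1), the T/S/D off-rate factors
#' at their dwell-time prior modes, and the KaiA affinity for the
#' ADP-bound U state is set orders of magnitude tighter than for any
#' other state, which makes the unphosphorylated pool a stoichiometric
#' KaiA trap. Exchange and hydrolysis rates are chosen so that the
#' system (i) phosphorylates to a plateau within 24 h at 1.5 uM KaiA and
#' 100\% ATP, (ii) autodephosphorylates completely without KaiA, and
#' (iii) shows a threshold-hyperbolic total-phosphorylation
#' stimulus-response curve in KaiA.
#'
#' @param noise_sd Noise level recorded with the truth (percentage
#'   points).
#' @return List with `params` (a `kai_params`) and `noise_sd`.
#' @export
kai_default_truth <- function(noise_sd = 2) {
  delta <- c(
    # ADP-bound U binds KaiA ~3 orders of magnitude tighter than baseline
    # (sub-nanomolar Kd): the unphosphorylated ADP-loaded pool is a
    # stoichiometric KaiA trap
    dka_U_DP = 1.0, dkb_U_DP = -2.5,
    # ADP-bound D is a good KaiA substrate too (exchange locks in D)
    dka_D_DP = 1.0, dka_D_TP = 0.0,
    # off-rate factors at the dwell-time prior modes (tau 1.0/0.43/0.26 s)
    dkb_T_DP = 1.1785, dkb_T_TP = 1.1785,
    dkb_S_DP = 1.545, dkb_S_TP = 1.545,
    dkb_D_DP = 1.763, dkb_D_TP = 1.763,
    # phosphorylation ordering: U -> T preferred over U -> S
    dkp_US = -1.0, dkd_SU = 0.0,
    dkp_TD = 0.3, dkd_DT = -0.5,
    dkp_SD = 0.3, dkd_DS = 0.5,
    # KaiA-bound phosphotransfer slightly enhanced
    dkpA_UT = 0.5, dkdA_TU = 0.0,
    dkpA_TD = 0.5, dkdA_DT = -0.5,
    dkpA_SD = 0.5, dkdA_DS = 0.0,
    dkpA_US = -0.5, dkdA_SU = 0.0,
    # hydrolysis slower on phosphorylated forms: the U futile cycle is the
    # dominant ATP sink, and phosphoforms revert via phosphotransfer of
    # the bound ADP rather than via their own hydrolysis
    dkh_T = -0.5, dkh_S = -0.5, dkh_D = -0.5,
    dkhA_U = 0.0, dkhA_T = 0.0, dkhA_S = 0.0, dkhA_D = 0.0,
    # exchange orders of magnitude faster on phosphorylated forms: the
    # trapped U pool exchanges slowly (futile against hydrolysis) while
    # free KaiA stabilizes T/S/D efficiently once the trap is saturated
    dkTPA_T = 3.1, dkTPA_S = 3.1, dkTPA_D = 3.1
  )
  params <- kai_params(
    base = c(kp = 2.5e-4, kd = 5e-4, ka = 0.0279, kb = 0.0663,
             krDP = 2e-3, kh = 5e-4),
    delta_log10 = delta,
    # uM^2 equivalent of the noise level; floored so the error model stays
    # proper when noiseless data are generated
    sigma2 = (max(noise_sd, 0.1) * 3.5 / 100)^2,
    init_frac = c(C_TP_U = 0.15, C_DP_U = 0.80, C_TP_T = 0.01,
                  C_DP_T = 0.01, C_TP_S = 0.01, C_DP_S = 0.01,
                  C_TP_D = 0.005))
  list(params = params, noise_sd = noise_sd)
}

#' Generate a synthetic kinetics dataset
#'
#' Simulates every phosphorylation condition of the design and the
#' two-stage dephosphorylation protocol under the ground-truth
#' parameters, records \%U, \%T and \%D (the S phosphoform is the
#' conservation-constrained observable and is never stored), adds i.i.d.
#' Gaussian noise with the design's single global standard deviation,
#' clips reported values to \[0, 100\], and attaches the hydrolysis-bound
#' metadata (applied to the three lowest KaiA levels at 100\% ATP).
#'
#' @param design A [kai_design()].
#' @param truth A [kai_default_truth()]-style list (`params`,
#'   `noise_sd`); the design's `noise_sd` is overridden by the truth's
#'   when both are present.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return A `kai_dataset` with attribute `truth`.
#' @export
kai_generate <- function(design = kai_design(), truth = kai_default_truth(),
                         seed = 1L) {
  stopifnot(inherits(design, "kai_design"))
  if (!inherits(truth$params, "kai_params")) {
    stop("truth must carry a valid kai_params object")
  }
  noise_sd <- if (!is.null(truth$noise_sd)) truth$noise_sd else
    design$noise_sd
  set.seed(seed)
  phos_forms <- c("U", "T", "D")
  recs <- list()
  for (a in design$kaiA_levels) {
    for (p in design$pctATP_levels) {
      cond <- kai_condition(kaiA_uM = a, pct_ATP = p,
                            kaiC_uM = design$kaiC_uM,
                            duration_h = max(design$phos_times))
      tr <- kai_simulate(truth$params, cond,
                         t_grid = sort(unique(c(0, design$phos_times))))
      if (is.null(tr)) stop("truth parameters failed to integrate at ",
                            "KaiA = ", a, ", %ATP = ", p)
      ph <- kai_observables(tr)$phosphoforms
      for (f in phos_forms) {
        y <- ph[[paste0("pct_", f)]][match(design$phos_times, ph$time_h)]
        recs[[length(recs) + 1L]] <- data.frame(
          condition_id = sprintf("phos_A%s_ATP%s", a, p),
          kaiA_uM = a, pct_ATP = p, protocol = "phosphorylation",
          time_h = design$phos_times, phosphoform = f, value_pct = y,
          stringsAsFactors = FALSE)
      }
    }
  }
  tr <- kai_simulate_dephosphorylation(
    truth$params, t_grid = sort(unique(c(0, design$dephos_times))))
  if (is.null(tr)) stop("truth parameters failed the dephosphorylation run")
  ph <- kai_observables(tr)$phosphoforms
  for (f in phos_forms) {
    recs[[length(recs) + 1L]] <- data.frame(
      condition_id = "dephos", kaiA_uM = 0, pct_ATP = 100,
      protocol = "dephosphorylation_two_stage",
      time_h = design$dephos_times, phosphoform = f,
      value_pct = ph[[paste0("pct_", f)]][match(design$dephos_times,
                                                ph$time_h)],
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  rec$value_pct <- pmin(100, pmax(0, rec$value_pct +
                                    stats::rnorm(nrow(rec), 0, noise_sd)))
  hyd_ids <- sprintf("phos_A%s_ATP%s", c(0.375, 0.75, 1.50), 100)
  hyd_ids <- intersect(hyd_ids, unique(rec$condition_id))
  hyd <- if (length(hyd_ids)) {
    kai_hydrolysis_bound(kaiC_uM = design$kaiC_uM,
                         condition_ids = hyd_ids)
  } else NULL
  ds <- kai_dataset(rec, kaiC_uM = design$kaiC_uM, hydrolysis = hyd)
  attr(ds, "truth") <- truth
  ds
}
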