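# Monomer-cycle oscillator for metabolic-compensation scans: a KaiC
# phosphoform cycle (U -> T -> D -> S -> U) with KaiA-stimulated
# Michaelis-Menten rate laws, KaiB-bound S/D states that sequester KaiA,
# a finite sequestration affinity K_D, and an optional ultrasensitive
# KaiA threshold on the phosphorylation drive.
#
# The base cycle rate constants are the classic measured monomer-cycle
# values (h^-1): each transition rate is k(A) = k0 + kA * A / (Khalf + A)
# with Khalf = 0.43 uM in active-KaiA monomer units. Phosphorylation
# steps scale with the ADP-to-ATP exchange efficiency
# pct/(pct + Krel*(100-pct)). These constants ship as a config list
# (kai_phong_config) so they can be versioned and replaced.

#' Default oscillator configuration
#'
#' Rate constants of the monomer phosphoform cycle (h^-1; `k0` basal, `kA`
#' KaiA-stimulated amplitude, MM half-saturation `Khalf` in uM), KaiB
#' binding/unbinding of the S phosphoform (`konB`, `koffB`, h^-1,
#' pseudo-first-order in excess KaiB), the KaiA-site stoichiometry of
#' sequestration-competent complexes (`seq_stoich`, KaiA monomers per
#' complex; `bd_sequesters` controls whether the D-state complex also
#' counts -- by default only the S-state complex does, since counting
#' both flattens the capacity feedback and quenches the limit cycle),
#' the relative ADP affinity of the nucleotide pocket (`atp_Krel`, < 1
#' means ATP is preferred, softening the \%ATP dependence of the
#' phosphorylation steps), and the threshold-patch coefficients
#' (`theta_c` dimensionless, `theta_a` offset; see
#' [kai_phong_threshold()]).
#'
#' @return A list of oscillator constants.
#' @export
kai_phong_config <- function() {
  list(
    Khalf = 0.43,
    k0 = c(UT = 0, US = 0, TD = 0, SD = 0,
           TU = 0.21, DT = 0, DS = 0.31, SU = 0.11),
    kA = c(UT = 0.479077, US = 0.0532308, TD = 0.212923, SD = 0.505692,
           TU = 0.0798462, DT = 0.173, DS = -0.319385, SU = -0.133077),
    konB = 30, koffB = 0.5,
    seq_stoich = 2, bd_sequesters = FALSE,
    atp_Krel = 0.25,
    theta_c = 0.2, theta_a = 0.05
  )
}

#' Active KaiA under finite-affinity sequestration
#'
#' KaiA binding to the sequestration sites on KaiB-bound KaiC is treated
#' as a one-site quasi-equilibrium with dissociation constant `K_D`: the
#' bound amount solves `B^2 - (A_total + capacity + K_D) B + A_total *
#' capacity = 0` (the physical root below `min(A_total, capacity)`), and
#' active KaiA is what remains. `K_D = 0` recovers the infinite-affinity
#' min-rule `active = max(0, A_total - capacity)`.
#'
#' @param A_total Total KaiA (uM).
#' @param capacity Sequestration capacity (uM of KaiA-binding sites).
#' @param K_D Sequestration dissociation constant (uM).
#' @return Active (unsequestered) KaiA, uM.
#' @examples
#' kai_active_kaiA(1, 1, 1)  # 1 - (3 - sqrt(5))/2 ~ 0.618
#' @export
kai_active_kaiA <- function(A_total, capacity, K_D) {
  if (any(c(A_total, capacity, K_D) < 0)) stop("inputs must be non-negative")
  if (K_D == 0) return(pmax(0, A_total - capacity))
  s <- A_total + capacity + K_D
  bound <- (s - sqrt(s^2 - 4 * A_total * capacity)) / 2
  A_total - bound
}

#' Ultrasensitive KaiA threshold
#'
#' The phenomenological phosphorylation threshold: substrate competition
#' by the unphosphorylated pool means a finite amount of active KaiA must
#' accumulate before phosphorylation responds, and the threshold grows
#' both with the U concentration and as \%ATP falls (mirroring the \%ATP
#' scaling of the stimulus-response EC50). The default form is
#' `theta = theta_c * C_U * (theta_a + (100 - pct_ATP)/100)`;
#' it is a declared stand-in, replaceable through the config.
#'
#' @param C_U U-phosphoform concentration (uM).
#' @param pct_ATP Solution \%ATP.
#' @param config [kai_phong_config()] list.
#' @return Threshold theta in uM of KaiA.
#' @export
kai_phong_threshold <- function(C_U, pct_ATP, config = kai_phong_config()) {
  config$theta_c * C_U * (config$theta_a + (100 - pct_ATP) / 100)
}

#' Effective phosphorylation drive after the threshold patch
#'
#' `max(0, active_A - theta)`, fed to the unchanged Michaelis-Menten rate
#' form. With `theta = 0` the patch is the identity.
#' @param active_A Active KaiA (uM).
#' @param theta Threshold (uM).
#' @return Effective KaiA drive (uM).
#' @export
kai_phong_drive <- function(active_A, theta) pmax(0, active_A - theta)

# right-hand side of the oscillator ODEs; y = (U, T, D, S, BS, BD)
.phong_rhs <- function(t, y, p) {
  U <- y[1]; T_ <- y[2]; D <- y[3]; S <- y[4]; BS <- y[5]; BD <- y[6]
  # sequestration-competent complexes: the S-state complex by default;
  # the D-state complex can be included but flattens the capacity's
  # dependence on S and quenches the limit cycle (see vignette)
  cap <- p$seq_stoich * (BS + if (isTRUE(p$bd_sequesters)) BD else 0)
  A_act <- kai_active_kaiA(p$A_total, cap, p$K_D)
  A_drive <- if (p$patched) {
    kai_phong_drive(A_act, kai_phong_threshold(U, p$pct_ATP, p))
  } else A_act
  mm_p <- A_drive / (p$Khalf + A_drive) # phosphorylation steps (patched)
  mm_d <- A_act / (p$Khalf + A_act)     # other KaiA-modulated steps
  # exchange efficiency: relative ADP affinity atp_Krel < 1 means ATP is
  # preferred at the nucleotide pocket, softening the %ATP dependence
  f_atp <- p$pct_ATP / (p$pct_ATP + p$atp_Krel * (100 - p$pct_ATP))
  k <- function(nm, mm) p$k0[[nm]] + p$kA[[nm]] * mm
  kUT <- f_atp * k("UT", mm_p); kUS <- f_atp * k("US", mm_p)
  kTD <- f_atp * k("TD", mm_p); kSD <- f_atp * k("SD", mm_p)
  kTU <- k("TU", mm_d); kDT <- k("DT", mm_d)
  kDS <- k("DS", mm_d); kSU <- k("SU", mm_d)
  # KaiB binds the S phosphoform; the bound complex keeps
  # (de)phosphorylating (BS <-> BD), and KaiB is released either by
  # unbinding or when the bound S dephosphorylates back to U
  dU <- kTU * T_ + kSU * S - (kUT + kUS) * U + kSU * BS
  dT <- kUT * U + kDT * D - (kTU + kTD) * T_
  dD <- kTD * T_ + kSD * S - (kDT + kDS) * D
  dS <- kUS * U + kDS * D - (kSU + kSD) * S - p$konB * S + p$koffB * BS
  dBS <- p$konB * S + kDS * BD - (p$koffB + kSD + kSU) * BS
  dBD <- kSD * BS - kDS * BD
  list(c(dU, dT, dD, dS, dBS, dBD))
}

#' Simulate the oscillator and classify its behavior
#'
#' Integrates the monomer-cycle model for `t_total` hours from an
#' all-unphosphorylated start, discards the first `t_discard` hours as
#' transient, resamples the total phosphorylation `C_P = T + S + D + BS +
#' BD` at 0.1 h, and classifies: standard deviation of `C_P` below 0.1 uM
#' is a weak oscillation; a trough-amplitude standard deviation above
#' 0.001 uM is a damped oscillation; fewer than 3 troughs is an
#' abnormally long period. Otherwise the mean trough-to-trough time is
#' the period. Troughs are local minima with prominence >= 0.01 uM.
#'
#' @param pct_ATP Solution \%ATP.
#' @param K_D KaiA sequestration dissociation constant (uM).
#' @param patched Apply the ultrasensitive threshold patch?
#' @param kaiC_uM,kaiA_uM Total concentrations (uM); defaults 3.5 and 1.5.
#' @param config [kai_phong_config()] list.
#' @param t_total,t_discard Simulation and discarded transient (hours).
#' @return A `kai_oscillation_report`: list with `period` (hours, `NA`
#'   unless oscillatory), `classification` (`"oscillatory"`, `"weak"`,
#'   `"damped"`, `"too_few_troughs"`, or `"invalid"`), `trough_times`,
#'   `trough_values`, and the resampled `time_h` / `C_P` series.
#' @export
kai_phong_simulate <- function(pct_ATP, K_D, patched = FALSE,
                               kaiC_uM = 3.5, kaiA_uM = 1.5,
                               config = kai_phong_config(),
                               t_total = 200, t_discard = 100) {
  p <- c(config, list(pct_ATP = pct_ATP, K_D = K_D, patched = patched,
                      A_total = kaiA_uM))
  y0 <- c(U = kaiC_uM, T = 0, D = 0, S = 0, BS = 0, BD = 0)
  times <- seq(0, t_total, by = 0.1)
  sol <- try(deSolve::ode(y0, times, .phong_rhs, p, method = "bdf",
                          rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
      any(!is.finite(sol))) {
    return(structure(list(period = NA_real_, classification = "invalid",
                          trough_times = numeric(0),
                          trough_values = numeric(0),
                          time_h = numeric(0), C_P = numeric(0)),
                     class = "kai_oscillation_report"))
  }
  keep <- sol[, "time"] >= t_discard
  tt <- sol[keep, "time"]
  cp <- rowSums(sol[keep, c("T", "S", "D", "BS", "BD"), drop = FALSE])
  kai_classify_oscillation(tt, cp)
}

#' Classify an oscillation from a resampled time series
#'
#' The analysis half of [kai_phong_simulate()], exposed separately so the
#' trough-detection and period pipeline can be checked against synthetic
#' signals of known period.
#'
#' @param time_h Time grid (hours; assumed the post-transient window).
#' @param C_P Total-phosphorylation series (uM).
#' @param prominence Trough prominence threshold (uM).
#' @return A `kai_oscillation_report` (see [kai_phong_simulate()]).
#' @export
kai_classify_oscillation <- function(time_h, C_P, prominence = 0.01) {
  n <- length(C_P)
  stopifnot(n == length(time_h), n >= 5L)
  troughs <- integer(0)
  i <- 2L
  while (i < n) {
    # local minimum (flat-bottomed minima take their first index)
    if (C_P[i] < C_P[i - 1L] && C_P[i] <= C_P[i + 1L]) {
      j <- i
      while (j < n && C_P[j + 1L] == C_P[i]) j <- j + 1L
      if (j < n && C_P[j + 1L] > C_P[i]) {
        # prominence: lower of the highest bars reached on each side
        # before a deeper value occurs
        left <- C_P[seq_len(i - 1L)]
        right <- C_P[seq.int(j + 1L, n)]
        lb <- which(left < C_P[i]); rb <- which(right < C_P[i])
        lmax <- if (length(lb)) max(left[seq.int(max(lb) + 1L,
                                                 i - 1L)]) else max(left)
        rmax <- if (length(rb)) max(right[seq_len(min(rb) - 1L)]) else
          max(right)
        if (min(lmax, rmax) - C_P[i] >= prominence) {
          troughs <- c(troughs, i)
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  tt <- time_h[troughs]; tv <- C_P[troughs]
  cls <- if (stats::sd(C_P) < 0.1) "weak"
  else if (length(troughs) < 3L) "too_few_troughs"
  else if (stats::sd(tv) > 0.001) "damped"
  else "oscillatory"
  period <- if (cls == "oscillatory") mean(diff(tt)) else NA_real_
  structure(list(period = period, classification = cls,
                 trough_times = tt, trough_values = tv,
                 time_h = time_h, C_P = C_P),
            class = "kai_oscillation_report")
}

#' Scan oscillator behavior over %ATP and K_D
#'
#' @param pct_ATP_grid,K_D_grid Grids (K_D typically log-spaced).
#' @param patched Apply the threshold patch?
#' @param ... Passed to [kai_phong_simulate()].
#' @return List with matrices `period` and `classification`
#'   (`pct_ATP` rows x `K_D` columns), the grids, and
#'   `n_oscillatory`.
#' @export
kai_phong_scan <- function(pct_ATP_grid, K_D_grid, patched = FALSE, ...) {
  np <- length(pct_ATP_grid); nk <- length(K_D_grid)
  period <- matrix(NA_real_, np, nk,
                   dimnames = list(pct_ATP_grid, signif(K_D_grid, 3)))
  cls <- matrix(NA_character_, np, nk,
                dimnames = dimnames(period))
  for (i in seq_len(np)) {
    for (j in seq_len(nk)) {
      rep_ij <- kai_phong_simulate(pct_ATP_grid[i], K_D_grid[j],
                                   patched = patched, ...)
      period[i, j] <- rep_ij$period
      cls[i, j] <- rep_ij$classification
    }
  }
  list(period = period, classification = cls,
       pct_ATP_grid = pct_ATP_grid, K_D_grid = K_D_grid,
       n_oscillatory = sum(cls == "oscillatory"))
}
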