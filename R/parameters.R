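# Parameterization: six base rate constants, 34 free log10 multiplicative
# state-dependence factors (Delta-k), 4 Delta-k derived from detailed
# balance, a global error variance hyperparameter, and 7 free initial
# fractions. 6 + 34 + 1 + 7 = 48 free scalars.

#' Names of the base rate constants
#'
#' `kp`/`kd`: phosphotransfer forward/backward (anchored to the U<->T
#' reaction without KaiA); `ka`/`kb`: KaiA on (s^-1 uM^-1, dimer) / off;
#' `krDP`: ADP release during KaiA-catalyzed nucleotide exchange;
#' `kh`: CII ATP hydrolysis. All first-order rates in s^-1.
#' @return Character vector of length 6.
#' @export
kai_base_names <- function() c("kp", "kd", "ka", "kb", "krDP", "kh")

#' Names of the 34 free Delta-k factors
#'
#' Multiplicative modifiers of the base rates, estimated in log10 space.
#' Reactions without a listed factor use the bare base rate (Delta-k = 1):
#' the U phosphoform is the hydrolysis/exchange baseline, the ATP-bound U
#' state is the KaiA on/off baseline, and the U<->T pair without KaiA is
#' the phosphotransfer anchor.
#' @return Character vector of length 34.
#' @export
kai_delta_names <- function() {
  c(
    # nucleotide exchange (KaiA-bound ADP states only)
    "dkTPA_T", "dkTPA_S", "dkTPA_D",
    # hydrolysis, free states (U baseline)
    "dkh_T", "dkh_S", "dkh_D",
    # hydrolysis, KaiA-bound states
    "dkhA_U", "dkhA_T", "dkhA_S", "dkhA_D",
    # KaiA on (U,TP baseline)
    "dka_U_DP", "dka_D_DP", "dka_D_TP",
    # KaiA off (U,TP baseline)
    "dkb_U_DP", "dkb_T_DP", "dkb_S_DP", "dkb_D_DP",
    "dkb_T_TP", "dkb_S_TP", "dkb_D_TP",
    # phosphotransfer without KaiA (U<->T anchored at 1)
    "dkp_US", "dkd_SU", "dkp_TD", "dkd_DT", "dkp_SD", "dkd_DS",
    # phosphotransfer with KaiA bound
    "dkpA_UT", "dkdA_TU", "dkpA_TD", "dkdA_DT",
    "dkpA_SD", "dkdA_DS", "dkpA_US", "dkdA_SU"
  )
}

#' Names of the 4 detailed-balance-derived Delta-k factors
#'
#' KaiA on-rate factors for the T and S phosphoforms; never free, always
#' computed by [kai_detailed_balance()].
#' @return Character vector of length 4.
#' @export
kai_derived_delta_names <- function() {
  c("dka_S_TP", "dka_T_TP", "dka_T_DP", "dka_S_DP")
}

# Initial-condition order (KaiA-free states at t = 0, Dirichlet order):
# the 8th fraction (C_DP_D) is fixed by conservation.
kai_init_names <- function() {
  c("C_TP_U", "C_DP_U", "C_TP_T", "C_DP_T", "C_TP_S", "C_DP_S", "C_TP_D")
}

#' Construct a rate parameter set
#'
#' Bundles the six base rate constants, the 34 free log10 Delta-k factors,
#' the global error variance and the seven free initial fractions into a
#' validated `kai_params` object. The four dependent KaiA-on factors are
#' computed from detailed balance at construction time.
#'
#' @param base Named numeric vector of the 6 base rates (natural units,
#'   s^-1; `ka` in s^-1 uM^-1). See [kai_base_names()].
#' @param delta_log10 Named numeric vector of the 34 free factors in log10
#'   units; missing names default to 0 (factor 1). See [kai_delta_names()].
#' @param sigma2 Global error variance hyperparameter (uM^2).
#' @param init_frac Named numeric vector of the 7 free initial fractions
#'   (KaiA-free states; the eighth, `C_DP_D`, is 1 minus their sum).
#' @return An object of class `kai_params`.
#' @examples
#' p <- kai_params()
#' p$derived_delta_log10   # all 0 when every free Delta-k is 1
#' @export
kai_params <- function(base = c(kp = 1e-4, kd = 1e-4, ka = 0.0279,
                                kb = 0.0663, krDP = 0.1, kh = 3e-4),
                       delta_log10 = NULL,
                       sigma2 = 0.01,
                       init_frac = NULL) {
  bn <- kai_base_names()
  if (!all(bn %in% names(base))) stop("base must name all of: ",
                                      paste(bn, collapse = ", "))
  base <- base[bn]
  if (any(!is.finite(base)) || any(base < 0)) {
    stop("base rates must be finite and non-negative")
  }
  dn <- kai_delta_names()
  dl <- stats::setNames(numeric(length(dn)), dn)
  if (!is.null(delta_log10)) {
    unknown <- setdiff(names(delta_log10), dn)
    if (length(unknown)) stop("unknown Delta-k names: ",
                              paste(unknown, collapse = ", "))
    if (any(!is.finite(delta_log10))) stop("Delta-k values must be finite")
    dl[names(delta_log10)] <- delta_log10
  }
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  inn <- kai_init_names()
  fr <- stats::setNames(c(0.15, 0.80, 0.01, 0.01, 0.01, 0.01, 0.005), inn)
  if (!is.null(init_frac)) {
    unknown <- setdiff(names(init_frac), inn)
    if (length(unknown)) stop("unknown initial-condition names: ",
                              paste(unknown, collapse = ", "))
    fr[names(init_frac)] <- init_frac
  }
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    stop("initial fractions must be in [0,1] and sum to at most 1")
  }
  obj <- structure(
    list(base = base, delta_log10 = dl,
         derived_delta_log10 = kai_detailed_balance(dl),
         sigma2 = sigma2, init_frac = fr),
    class = "kai_params"
  )
  obj
}

#' @export
print.kai_params <- function(x, ...) {
  cat("<kai_params> 48 free scalars",
      "(6 base rates, 34 log10 Delta-k, sigma2, 7 init fractions)\n")
  cat("base rates (s^-1; ka s^-1 uM^-1):\n")
  print(signif(x$base, 4))
  cat("sigma2 =", signif(x$sigma2, 4),
      "uM^2; nonzero Delta-k:", sum(x$delta_log10 != 0), "of 34\n")
  invisible(x)
}

#' Detailed-balance completion of the KaiA on-rate factors
#'
#' Every reversible four-state cycle of the network (two phosphotransfer-
#' linked KaiA-free states plus their KaiA-bound counterparts) must have
#' zero free-energy change, i.e. the product of the forward rate constants
#' around the cycle equals the product of the reverse ones. Each of the
#' four such cycles fixes one KaiA-on factor in terms of the free factors;
#' this function solves those four constraints (in log10 space).
#'
#' @param delta_log10 Named numeric vector of the 34 free log10 factors.
#' @return Named numeric vector of the 4 derived log10 factors
#'   (`dka_S_TP`, `dka_T_TP`, `dka_T_DP`, `dka_S_DP`).
#' @examples
#' kai_detailed_balance(setNames(numeric(34), kai_delta_names()))
#' @export
kai_detailed_balance <- function(delta_log10) {
  d <- delta_log10
  if (!all(kai_delta_names() %in% names(d))) {
    stop("all 34 free Delta-k values must be supplied")
  }
  if (any(!is.finite(d))) stop("Delta-k values must be finite")
  c(
    # cycle C_TP_S -> C_DP_D -> AC_DP_D -> AC_TP_S -> C_TP_S
    dka_S_TP = unname(d["dkp_SD"] + d["dka_D_DP"] + d["dkdA_DS"] +
                        d["dkb_S_TP"] - d["dkpA_SD"] - d["dkb_D_DP"] -
                        d["dkd_DS"]),
    # cycle C_TP_T -> C_DP_D -> AC_DP_D -> AC_TP_T -> C_TP_T
    dka_T_TP = unname(d["dkp_TD"] + d["dka_D_DP"] + d["dkdA_DT"] +
                        d["dkb_T_TP"] - d["dkpA_TD"] - d["dkb_D_DP"] -
                        d["dkd_DT"]),
    # cycle C_TP_U -> C_DP_T -> AC_DP_T -> AC_TP_U -> C_TP_U
    # (U<->T without KaiA is the Delta-k = 1 anchor)
    dka_T_DP = unname(d["dkpA_UT"] + d["dkb_T_DP"] - d["dkdA_TU"]),
    # cycle C_TP_U -> C_DP_S -> AC_DP_S -> AC_TP_U -> C_TP_U
    dka_S_DP = unname(d["dkpA_US"] + d["dkb_S_DP"] + d["dkd_SU"] -
                        d["dkp_US"] - d["dkdA_SU"])
  )
}

#' Detailed-balance cycle definitions
#'
#' Each row lists one reversible cycle as the ordered quadruple of state
#' labels; used by tests to multiply the actual per-reaction rates around
#' each cycle as an independent check on [kai_detailed_balance()].
#' @return A list of 4 character vectors of state labels (cycle order:
#'   free TP state, free DP state, bound DP state, bound TP state).
#' @export
kai_balance_cycles <- function() {
  list(
    c("C_TP_S", "C_DP_D", "AC_DP_D", "AC_TP_S"),
    c("C_TP_T", "C_DP_D", "AC_DP_D", "AC_TP_T"),
    c("C_TP_U", "C_DP_T", "AC_DP_T", "AC_TP_U"),
    c("C_TP_U", "C_DP_S", "AC_DP_S", "AC_TP_U")
  )
}

#' Pack a parameter set into the 48 sampler coordinates
#'
#' The free coordinates, in order: log10 of the 6 base rates, the 34 log10
#' Delta-k factors, sigma2 (natural scale) and the 7 free initial
#' fractions. This is the coordinate system walked by the MCMC ensemble.
#'
#' @param params A `kai_params` object.
#' @return Named numeric vector of length 48.
#' @export
kai_pack <- function(params) {
  stopifnot(inherits(params, "kai_params"))
  c(stats::setNames(log10(params$base), paste0("log10_", kai_base_names())),
    params$delta_log10,
    sigma2 = unname(params$sigma2),
    stats::setNames(params$init_frac, paste0("f0_", kai_init_names())))
}

#' Unpack sampler coordinates into a parameter set
#'
#' Inverse of [kai_pack()]. Returns `NULL` (rather than erroring) when the
#' coordinates are invalid (non-positive sigma2, fractions off the
#' simplex), so samplers can map the point to log-posterior -Inf.
#'
#' @param theta Numeric vector of length 48 in [kai_pack()] order.
#' @return A `kai_params` object, or `NULL` for invalid coordinates.
#' @export
kai_unpack <- function(theta) {
  if (length(theta) != 48L || any(!is.finite(theta))) return(NULL)
  base <- 10^theta[1:6]
  names(base) <- kai_base_names()
  dl <- theta[7:40]
  names(dl) <- kai_delta_names()
  sigma2 <- unname(theta[41])
  fr <- theta[42:48]
  names(fr) <- kai_init_names()
  if (sigma2 <= 0 || any(fr < 0) || sum(fr) > 1) return(NULL)
  kai_params(base = base, delta_log10 = dl, sigma2 = sigma2, init_frac = fr)
}

#' Serialize a parameter set to JSON
#'
#' Flat key/value JSON: natural values for the base rates, sigma2 and the
#' initial fractions, log10 values for the Delta-k factors (free and,
#' under `"derived"`, the detailed-balance-dependent ones).
#'
#' @param params A `kai_params` object.
#' @param path File to write; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
kai_params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "kai_params"))
  x <- c(as.list(params$base), as.list(params$delta_log10),
         list(sigma2 = params$sigma2),
         as.list(stats::setNames(params$init_frac,
                                 paste0("f0_", kai_init_names()))),
         list(derived = as.list(params$derived_delta_log10)))
  if (is.null(path)) {
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set from JSON written by [kai_params_to_json()]
#' @param path Path to the JSON file.
#' @return A `kai_params` object.
#' @export
kai_params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- unlist(x[kai_base_names()])
  dl <- unlist(x[kai_delta_names()])
  fr <- unlist(x[paste0("f0_", kai_init_names())])
  names(fr) <- kai_init_names()
  kai_params(base = base, delta_log10 = dl, sigma2 = x$sigma2,
             init_frac = fr)
}
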