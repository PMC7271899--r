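# Reduced model variants: tie the KaiA on/off Delta-k factors across the
# nucleotide-bound state (-n), across the phosphoform (-p), or both
# (-n,-p), keeping the same reaction network. Detailed balance is
# re-derived for each reduced parameterization: the four cycle constraints
# still eliminate one parameter each, but once the KaiA factors are tied
# some constraints fall on the KaiA-bound phosphotransfer factors instead.

#' Construct a reduced model variant
#'
#' @param name One of `"full"`, `"minus_n"` (KaiA on/off independent of
#'   the nucleotide-bound state), `"minus_p"` (independent of the
#'   phosphoform), `"minus_n_p"` (a single on/off pair: the base `ka` and
#'   `kb` themselves).
#' @return A `kai_variant` list with `name`, `free_delta` (names of the
#'   variant's free Delta-k coordinates) and `expand`, a function mapping
#'   a named vector over `free_delta` to the full 34-entry log10 Delta-k
#'   vector with every tie and detailed-balance constraint applied.
#' @examples
#' v <- kai_variant("minus_n_p")
#' length(v$free_delta)   # 20
#' @export
kai_variant <- function(name = c("full", "minus_n", "minus_p",
                                 "minus_n_p")) {
  name <- match.arg(name)
  full <- kai_delta_names()
  zero34 <- stats::setNames(numeric(34), full)
  shared <- c("dkTPA_T", "dkTPA_S", "dkTPA_D",
              "dkh_T", "dkh_S", "dkh_D",
              "dkhA_U", "dkhA_T", "dkhA_S", "dkhA_D",
              "dkp_US", "dkd_SU", "dkp_TD", "dkd_DT", "dkp_SD", "dkd_DS")
  if (name == "full") {
    free <- full
    expand <- function(d) {
      out <- zero34; out[names(d)] <- d; out
    }
  } else if (name == "minus_n") {
    # one on/off pair per phosphoform; U's pair is the base ka/kb itself.
    # Cycles through U fix the T and S on-factors; the remaining two
    # cycles then determine dkpA_TD and dkpA_SD.
    free <- c(shared, "dka_D", "dkb_T", "dkb_S", "dkb_D",
              "dkpA_UT", "dkdA_TU", "dkdA_DT", "dkdA_DS",
              "dkpA_US", "dkdA_SU")
    expand <- function(d) {
      out <- zero34
      out[intersect(names(d), full)] <- d[intersect(names(d), full)]
      out["dka_D_DP"] <- out["dka_D_TP"] <- d["dka_D"]
      for (X in c("T", "S", "D")) {
        out[paste0("dkb_", X, "_DP")] <- out[paste0("dkb_", X, "_TP")] <-
          d[paste0("dkb_", X)]
      }
      dka_T <- d["dkpA_UT"] + d["dkb_T"] - d["dkdA_TU"]
      dka_S <- d["dkpA_US"] + d["dkb_S"] + d["dkd_SU"] -
        d["dkp_US"] - d["dkdA_SU"]
      out["dkpA_TD"] <- d["dkp_TD"] + d["dka_D"] + d["dkdA_DT"] +
        d["dkb_T"] - d["dkb_D"] - d["dkd_DT"] - dka_T
      out["dkpA_SD"] <- d["dkp_SD"] + d["dka_D"] + d["dkdA_DS"] +
        d["dkb_S"] - d["dkb_D"] - d["dkd_DS"] - dka_S
      out
    }
  } else if (name == "minus_p") {
    # one on/off pair per nucleotide state; the ATP-bound pair is the base
    # ka/kb. All four cycle constraints fall on KaiA-bound phosphotransfer.
    free <- c(shared, "dka_DP", "dkb_DP", "dkdA_TU", "dkdA_DT", "dkdA_DS",
              "dkdA_SU")
    expand <- function(d) {
      out <- zero34
      out[intersect(names(d), full)] <- d[intersect(names(d), full)]
      out["dka_U_DP"] <- out["dka_D_DP"] <- d["dka_DP"]
      out["dka_D_TP"] <- 0
      for (X in c("U", "T", "S", "D")) {
        if (X != "U") out[paste0("dkb_", X, "_TP")] <- 0
        out[paste0("dkb_", X, "_DP")] <- d["dkb_DP"]
      }
      out["dkpA_UT"] <- d["dka_DP"] - d["dkb_DP"] + d["dkdA_TU"]
      out["dkpA_US"] <- d["dka_DP"] - d["dkb_DP"] - d["dkd_SU"] +
        d["dkp_US"] + d["dkdA_SU"]
      out["dkpA_TD"] <- d["dkp_TD"] + d["dka_DP"] + d["dkdA_DT"] -
        d["dkb_DP"] - d["dkd_DT"]
      out["dkpA_SD"] <- d["dkp_SD"] + d["dka_DP"] + d["dkdA_DS"] -
        d["dkb_DP"] - d["dkd_DS"]
      out
    }
  } else { # minus_n_p
    # a single KaiA on/off pair: base ka and kb; every Delta-ka/b is 1.
    free <- c(shared, "dkdA_TU", "dkdA_DT", "dkdA_DS", "dkdA_SU")
    expand <- function(d) {
      out <- zero34
      out[intersect(names(d), full)] <- d[intersect(names(d), full)]
      out["dkpA_UT"] <- d["dkdA_TU"]
      out["dkpA_US"] <- d["dkp_US"] + d["dkdA_SU"] - d["dkd_SU"]
      out["dkpA_TD"] <- d["dkp_TD"] + d["dkdA_DT"] - d["dkd_DT"]
      out["dkpA_SD"] <- d["dkp_SD"] + d["dkdA_DS"] - d["dkd_DS"]
      out
    }
  }
  structure(list(name = name, free_delta = free, expand = expand),
            class = "kai_variant")
}

#' Project a full parameter set onto a variant
#'
#' Builds the variant-constrained set matched to a full parameter set:
#' every tied group of KaiA on/off factors is collapsed to its log10 mean
#' (the geometric mean of the rates), so each phosphoform (for
#' `minus_n`) or each nucleotide state (for `minus_p`) keeps its mean
#' KaiA on and off rate while losing the within-group differential.
#' Because the variants anchor one tied pair to the base `ka`/`kb`, the
#' base rates are rescaled by the anchor group's mean factor and all
#' other tied factors are shifted to compensate, which leaves every
#' non-anchor rate at its group mean. Detailed balance is re-applied
#' through the variant's own constraint structure. Useful for matched
#' comparisons between a full fit and its nucleotide- or phosphoform-tied
#' reduction (the tied set is what the full set "looks like" with the
#' differential affinity removed).
#'
#' @param params A full `kai_params`.
#' @param variant A `kai_variant` (or variant name).
#' @param anchor `"baseline"` (default) leaves the variant's anchor group
#'   (the tied pair absorbed into the base `ka`/`kb`) at the bare base
#'   rates, so e.g. the `minus_n` projection's U phosphoform binds with
#'   the baseline affinity of the full model's ATP-bound U state --
#'   removing the differential removes the tight ADP-form binding that the
#'   differential created. `"mean"` instead rescales the base `ka`/`kb` by
#'   the anchor group's mean factor, so every tied group (anchor
#'   included) keeps its geometric-mean on and off rate.
#' @return A `kai_params` satisfying the variant's ties.
#' @export
kai_variant_project <- function(params, variant,
                                anchor = c("baseline", "mean")) {
  if (is.character(variant)) variant <- kai_variant(variant)
  anchor <- match.arg(anchor)
  stopifnot(inherits(params, "kai_params"), inherits(variant, "kai_variant"))
  d <- params$delta_log10
  dd <- params$derived_delta_log10
  g <- function(...) mean(c(...)) # log10 mean = geometric mean of rates
  fd <- stats::setNames(numeric(length(variant$free_delta)),
                        variant$free_delta)
  common <- intersect(variant$free_delta, names(d))
  fd[common] <- d[common]
  base <- params$base
  # anchor-group mean factors (log10); zero when anchoring to baseline
  sa <- sb <- 0
  if (variant$name == "minus_n") {
    if (anchor == "mean") {
      sa <- g(0, d["dka_U_DP"])
      sb <- g(0, d["dkb_U_DP"])
    }
    fd["dka_D"] <- g(d["dka_D_DP"], d["dka_D_TP"]) - sa
    fd["dkb_T"] <- g(d["dkb_T_DP"], d["dkb_T_TP"]) - sb
    fd["dkb_S"] <- g(d["dkb_S_DP"], d["dkb_S_TP"]) - sb
    fd["dkb_D"] <- g(d["dkb_D_DP"], d["dkb_D_TP"]) - sb
  } else if (variant$name == "minus_p") {
    if (anchor == "mean") {
      sa <- g(0, dd["dka_T_TP"], dd["dka_S_TP"], d["dka_D_TP"])
      sb <- g(0, d["dkb_T_TP"], d["dkb_S_TP"], d["dkb_D_TP"])
    }
    fd["dka_DP"] <- g(d["dka_U_DP"], d["dka_D_DP"], dd["dka_T_DP"],
                      dd["dka_S_DP"]) - sa
    fd["dkb_DP"] <- g(d["dkb_U_DP"], d["dkb_T_DP"], d["dkb_S_DP"],
                      d["dkb_D_DP"]) - sb
  } else if (variant$name == "minus_n_p") {
    if (anchor == "mean") {
      sa <- g(0, d["dka_U_DP"], dd["dka_T_TP"], dd["dka_T_DP"],
              dd["dka_S_TP"], dd["dka_S_DP"], d["dka_D_TP"], d["dka_D_DP"])
      sb <- g(0, d["dkb_U_DP"], d["dkb_T_TP"], d["dkb_T_DP"],
              d["dkb_S_TP"], d["dkb_S_DP"], d["dkb_D_TP"], d["dkb_D_DP"])
    }
  }
  base["ka"] <- base["ka"] * 10^sa
  base["kb"] <- base["kb"] * 10^sb
  kai_params(base = base, delta_log10 = variant$expand(fd),
             sigma2 = params$sigma2, init_frac = params$init_frac)
}
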