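#' The 16 KaiC states
#'
#' Each KaiC subunit (CII domain) is tracked by three properties: its
#' phosphoform (U, T, S, or D), the nucleotide occupying the catalytic
#' pocket (ATP, "TP", or ADP, "DP"), and whether a KaiA dimer is bound.
#' This yields 4 x 2 x 2 = 16 distinct states.
#'
#' The enumeration order is fixed: the eight KaiA-free states come first,
#' ordered by phosphoform (U, T, S, D) and, within each phosphoform, ATP-
#' before ADP-bound; the eight KaiA-bound states follow in the same order.
#' The first eight positions therefore match the order in which initial
#' conditions are parameterized (see [kai_params()]).
#'
#' @return A data frame with 16 rows and columns `label` (e.g. `"C_TP_U"`,
#'   `"AC_DP_D"`), `phos` (factor U/T/S/D), `nuc` (factor TP/DP), and
#'   `kaiA_bound` (logical).
#' @examples
#' st <- kai_states()
#' nrow(st)                      # 16
#' sum(!st$kaiA_bound)           # 8 KaiA-free states
#' @export
kai_states <- function() {
  phos <- c("U", "T", "S", "D")
  nuc <- c("TP", "DP")
  free <- expand.grid(nuc = nuc, phos = phos,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  st <- rbind(cbind(free, kaiA_bound = FALSE),
              cbind(free, kaiA_bound = TRUE))
  st$label <- paste0(ifelse(st$kaiA_bound, "AC_", "C_"), st$nuc, "_", st$phos)
  st$phos <- factor(st$phos, levels = phos)
  st$nuc <- factor(st$nuc, levels = nuc)
  st[, c("label", "phos", "nuc", "kaiA_bound")]
}

#' Index of a state in the canonical enumeration
#'
#' @param phos Phosphoform, one of `"U"`, `"T"`, `"S"`, `"D"`.
#' @param nuc Nucleotide-bound state, `"TP"` or `"DP"`.
#' @param kaiA_bound Logical; is a KaiA dimer bound?
#' @return Integer position in 1..16 (vectorized over arguments).
#' @export
kai_state_index <- function(phos, nuc, kaiA_bound) {
  ip <- match(phos, c("U", "T", "S", "D"))
  inuc <- match(nuc, c("TP", "DP"))
  if (anyNA(ip) || anyNA(inuc)) stop("unknown phosphoform or nucleotide label")
  as.integer((ip - 1L) * 2L + inuc + ifelse(kaiA_bound, 8L, 0L))
}

# Phosphotransfer pairs: C_TP_X <-> C_DP_Y. An ATP-bound subunit can only
# phosphorylate; an ADP-bound subunit can only dephosphorylate.
kai_transfer_pairs <- function() {
  data.frame(
    from = c("U", "U", "T", "S"),
    to   = c("T", "S", "D", "D"),
    stringsAsFactors = FALSE
  )
}
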