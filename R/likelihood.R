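# Likelihood: Gaussian on the phosphoform time series with a single global
# error sigma, a x4 weight on the dephosphorylation records, and a
# half-harmonic penalty enforcing the hydrolysis-rate upper bound.

#' Assemble a kinetics dataset
#'
#' @param records Data frame with columns `condition_id`, `kaiA_uM`,
#'   `pct_ATP`, `protocol` (`"phosphorylation"` or
#'   `"dephosphorylation_two_stage"`), `time_h`, `phosphoform` (one of
#'   `"U"`, `"T"`, `"D"`; S is never stored -- it is the
#'   conservation-constrained phosphoform), `value_pct`, and optionally
#'   `weight` (defaults to 1 for phosphorylation and
#'   `dephos_weight` for dephosphorylation records).
#' @param kaiC_uM Total KaiC concentration of the phosphorylation
#'   reactions (uM).
#' @param hydrolysis `NULL`, or a list with `bound_uM` (upper bound on ADP
#'   produced over 12 h, uM), `sigma_uM` (half-harmonic width) and
#'   `condition_ids` (which phosphorylation conditions it applies to).
#'   See [kai_hydrolysis_bound()].
#' @param dephos_weight Weight multiplying the full log-density of each
#'   dephosphorylation record (default 4).
#' @return A `kai_dataset` object.
#' @export
kai_dataset <- function(records, kaiC_uM = 3.5, hydrolysis = NULL,
                        dephos_weight = 4) {
  need <- c("condition_id", "kaiA_uM", "pct_ATP", "protocol", "time_h",
            "phosphoform", "value_pct")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (any(records$phosphoform == "S")) {
    stop("the S phosphoform is the conservation-constrained observable ",
         "and is never stored")
  }
  if (!all(records$phosphoform %in% c("U", "T", "D"))) {
    stop("phosphoform must be one of U, T, D")
  }
  if (!"weight" %in% names(records)) {
    records$weight <- ifelse(
      records$protocol == "dephosphorylation_two_stage", dephos_weight, 1)
  }
  conds <- unique(records[, c("condition_id", "kaiA_uM", "pct_ATP",
                              "protocol")])
  if (anyDuplicated(conds$condition_id)) {
    stop("condition_id must map to a unique (kaiA, pctATP, protocol) triple")
  }
  if (!is.null(hydrolysis)) {
    stopifnot(all(c("bound_uM", "sigma_uM", "condition_ids") %in%
                    names(hydrolysis)))
    if (!all(hydrolysis$condition_ids %in% conds$condition_id)) {
      stop("hydrolysis condition_ids must reference dataset conditions")
    }
  }
  structure(list(records = records, conditions = conds, kaiC_uM = kaiC_uM,
                 hydrolysis = hydrolysis),
            class = "kai_dataset")
}

#' Hydrolysis bound in concentration units
#'
#' Converts a per-KaiC daily ADP production rate into the total ADP (uM)
#' produced over a 12 h phosphorylation reaction: `rate_per_day * kaiC_uM *
#' (12/24)`. The default rate and uncertainty are the measured maximum CII
#' hydrolysis rate, 29.8 +/- 5.1 ADP per KaiC per day.
#'
#' @param rate_per_day Upper bound, ADP per KaiC per day.
#' @param sigma_per_day Uncertainty of the bound, same units (used as the
#'   half-harmonic width).
#' @param kaiC_uM Total KaiC (uM).
#' @param condition_ids Conditions the bound applies to.
#' @return List suitable for the `hydrolysis` argument of [kai_dataset()].
#' @export
kai_hydrolysis_bound <- function(rate_per_day = 29.8, sigma_per_day = 5.1,
                                 kaiC_uM = 3.5, condition_ids = character()) {
  list(bound_uM = rate_per_day * kaiC_uM * 0.5,
       sigma_uM = sigma_per_day * kaiC_uM * 0.5,
       condition_ids = condition_ids)
}

#' Model predictions for every dataset record
#'
#' Simulates each condition once (phosphorylation from the parameter
#' set's initial fractions; dephosphorylation through the two-stage
#' protocol) and reads off the predicted phosphoform percentage at each
#' record's time, plus the 12 h ADP production for the hydrolysis-bound
#' conditions.
#'
#' @param params A `kai_params` object.
#' @param dataset A `kai_dataset`.
#' @return List with `predicted` (numeric, aligned with
#'   `dataset$records`) and `ADP_uM` (named by hydrolysis condition id),
#'   or `NULL` if any integration fails.
#' @export
kai_predict <- function(params, dataset) {
  stopifnot(inherits(dataset, "kai_dataset"))
  rec <- dataset$records
  pred <- rep(NA_real_, nrow(rec))
  hyd_ids <- if (is.null(dataset$hydrolysis)) character() else
    dataset$hydrolysis$condition_ids
  adp <- stats::setNames(rep(NA_real_, length(hyd_ids)), hyd_ids)
  for (cid in dataset$conditions$condition_id) {
    ci <- dataset$conditions[dataset$conditions$condition_id == cid, ]
    ridx <- which(rec$condition_id == cid)
    times <- sort(unique(rec$time_h[ridx]))
    need_adp <- cid %in% hyd_ids
    if (ci$protocol == "phosphorylation") {
      grid <- sort(unique(c(0, times, if (need_adp) 12)))
      cond <- kai_condition(kaiA_uM = ci$kaiA_uM, pct_ATP = ci$pct_ATP,
                            kaiC_uM = dataset$kaiC_uM,
                            duration_h = max(grid))
      tr <- kai_simulate(params, cond, t_grid = grid)
    } else {
      grid <- sort(unique(c(0, times)))
      tr <- kai_simulate_dephosphorylation(params, t_grid = grid)
    }
    if (is.null(tr)) return(NULL)
    ob_full <- kai_observables(tr, adp_window_h = 12)
    ob <- ob_full$phosphoforms
    for (i in ridx) {
      j <- which.min(abs(ob$time_h - rec$time_h[i]))
      pred[i] <- ob[[paste0("pct_", rec$phosphoform[i])]][j]
    }
    if (need_adp) adp[cid] <- ob_full$ADP_produced_uM
  }
  list(predicted = pred, ADP_uM = adp)
}

#' Gaussian log-likelihood of the phosphoform time series
#'
#' Independent Gaussian errors with a single global standard deviation for
#' all (de)phosphorylation records. The error hyperparameter sigma2 is
#' carried in uM^2 and converted to percentage points through the total
#' KaiC of the dataset (`sigma_pct = sqrt(sigma2) * 100 / kaiC_uM`), since
#' observations are percentages of total KaiC. Each record's full log
#' density (quadratic and normalization term) is multiplied by its weight;
#' dephosphorylation records carry weight 4 by default.
#'
#' @param params A `kai_params`.
#' @param dataset A `kai_dataset`.
#' @param predictions Optional precomputed [kai_predict()] result.
#' @return Log-likelihood (`-Inf` on integration failure).
#' @export
kai_log_likelihood_timeseries <- function(params, dataset,
                                          predictions = NULL) {
  if (is.null(predictions)) predictions <- kai_predict(params, dataset)
  if (is.null(predictions)) return(-Inf)
  rec <- dataset$records
  sigma_pct <- sqrt(params$sigma2) * 100 / dataset$kaiC_uM
  ll <- stats::dnorm(rec$value_pct, predictions$predicted, sigma_pct,
                     log = TRUE)
  sum(rec$weight * ll)
}

#' Half-harmonic log-likelihood of the hydrolysis bound
#'
#' Zero while the model's 12 h ADP production stays below the experimental
#' upper bound; one-sided quadratic `-(ADP_model - ADP_exp)^2 / (2
#' sigma_h^2)` above it. Continuous and once-differentiable at the
#' junction.
#'
#' @param params A `kai_params`.
#' @param dataset A `kai_dataset` with a hydrolysis bound.
#' @param predictions Optional precomputed [kai_predict()] result.
#' @return Log-likelihood contribution (0 when the dataset carries no
#'   bound; `-Inf` on integration failure).
#' @export
kai_log_likelihood_hydrolysis <- function(params, dataset,
                                          predictions = NULL) {
  hb <- dataset$hydrolysis
  if (is.null(hb) || length(hb$condition_ids) == 0L) return(0)
  if (is.null(predictions)) predictions <- kai_predict(params, dataset)
  if (is.null(predictions)) return(-Inf)
  excess <- pmax(0, predictions$ADP_uM - hb$bound_uM)
  -sum(excess^2) / (2 * hb$sigma_uM^2)
}

#' Log-posterior (up to an additive constant)
#'
#' `log prior + weighted Gaussian time-series log-likelihood +
#' half-harmonic hydrolysis log-likelihood`. Integration failures and
#' out-of-support parameters map to `-Inf`.
#'
#' @param params A `kai_params` (or `NULL`, treated as invalid).
#' @param dataset A `kai_dataset`.
#' @param spec A `kai_prior_spec`.
#' @return List with `log_posterior`, `log_prior`, `log_lik_ts`,
#'   `log_lik_hydrolysis`.
#' @export
kai_log_posterior <- function(params, dataset, spec = kai_prior_spec()) {
  if (is.null(params)) {
    return(list(log_posterior = -Inf, log_prior = -Inf, log_lik_ts = -Inf,
                log_lik_hydrolysis = -Inf))
  }
  lp <- kai_log_prior(params, spec)
  if (!is.finite(lp)) {
    return(list(log_posterior = -Inf, log_prior = lp, log_lik_ts = NA_real_,
                log_lik_hydrolysis = NA_real_))
  }
  pr <- kai_predict(params, dataset)
  lts <- kai_log_likelihood_timeseries(params, dataset, pr)
  lh <- kai_log_likelihood_hydrolysis(params, dataset, pr)
  list(log_posterior = lp + lts + lh, log_prior = lp, log_lik_ts = lts,
       log_lik_hydrolysis = lh)
}

#' Read / write dataset CSV
#'
#' Column schema: `condition_id, kaiA_uM, pct_ATP, protocol, time_h,
#' phosphoform, value_pct, weight`. The hydrolysis bound travels in a
#' side-car JSON (`<path>.hydrolysis.json`) when present.
#'
#' @param dataset A `kai_dataset`.
#' @param path CSV path.
#' @return `path` invisibly ([kai_write_dataset()]); a `kai_dataset`
#'   ([kai_read_dataset()]).
#' @export
kai_write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "kai_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE)
  if (!is.null(dataset$hydrolysis)) {
    jsonlite::write_json(c(dataset$hydrolysis,
                           list(kaiC_uM = dataset$kaiC_uM)),
                         paste0(path, ".hydrolysis.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname kai_write_dataset
#' @export
kai_read_dataset <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".hydrolysis.json")
  hyd <- NULL
  kaiC <- 3.5
  if (file.exists(side)) {
    x <- jsonlite::read_json(side, simplifyVector = TRUE)
    hyd <- list(bound_uM = x$bound_uM, sigma_uM = x$sigma_uM,
                condition_ids = x$condition_ids)
    if (!is.null(x$kaiC_uM)) kaiC <- x$kaiC_uM
  }
  kai_dataset(rec, kaiC_uM = kaiC, hydrolysis = hyd)
}
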