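# Run configuration: the sampling/annealing/evidence constants, with a
# read-only "paper" profile holding the full-scale values and a "test"
# profile scaling every chain length down for desk-scale runs.

.kai_paper_profile <- function() {
  list(
    profile = "paper",
    n_walkers = 224L,
    anneal_betas = seq(0.3, 1.0, by = 0.1),
    anneal_steps = 20000L,
    sample_steps = 50000L,
    extra_steps = 50000L,
    alpha = 1.1,
    reseed_sd = 0.001,
    select_pool = 300L,
    select_k = 10L,
    reseed_beta = 0.6,
    improvement_tol = 1.0,
    powell_maxit = 100L,
    powell_line_tol = 1e-8,
    thin = 100L,
    post_window = 30000L,
    max_generations = 10L,
    evidence_lambda_step = 0.01,
    evidence_stage_steps = 2000L,
    evidence_use_last = 1000L
  )
}

#' Run configuration
#'
#' Returns the constants driving [kai_fit()] and [kai_log_evidence()]. The
#' `"paper"` profile carries the full-scale values (224 walkers, 8
#' annealing temperatures of 20,000 steps each, 50,000 sampling steps,
#' evidence ladder of 0.01 steps with 2,000-step stages); the `"test"`
#' profile scales all chain lengths down by >= 50x for quick runs while
#' keeping the same structure. Individual entries can be overridden, but
#' the walker count must always exceed the number of free parameters of
#' the problem it is used on (checked at fit time).
#'
#' @param profile `"paper"` or `"test"`.
#' @param ... Named overrides of individual entries (unknown names are an
#'   error).
#' @return A `kai_config` list.
#' @export
kai_config <- function(profile = c("paper", "test"), ...) {
  profile <- match.arg(profile)
  cfg <- .kai_paper_profile()
  if (profile == "test") {
    cfg$profile <- "test"
    cfg$n_walkers <- NA_integer_ # resolved to 2 x n_dims at fit time
    cfg$anneal_steps <- 60L
    cfg$sample_steps <- 200L
    cfg$extra_steps <- 100L
    cfg$select_pool <- 30L
    cfg$select_k <- 3L
    cfg$powell_maxit <- 4L
    cfg$powell_line_tol <- 1e-4
    cfg$thin <- 2L
    cfg$post_window <- 100L
    cfg$max_generations <- 3L
    cfg$evidence_lambda_step <- 0.1
    cfg$evidence_stage_steps <- 150L
    cfg$evidence_use_last <- 75L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (length(cfg$anneal_betas)) {
    if (is.unsorted(cfg$anneal_betas, strictly = TRUE) ||
        utils::tail(cfg$anneal_betas, 1) != 1.0) {
      stop("anneal_betas must be strictly increasing and end at 1.0")
    }
  }
  if (cfg$alpha <= 1) stop("alpha must exceed 1")
  structure(cfg, class = "kai_config")
}

#' Save / load a run configuration (round-trip JSON)
#' @param config A `kai_config`.
#' @param path JSON file path.
#' @return `path` invisibly; [kai_load_config()] returns a `kai_config`.
#' @export
kai_save_config <- function(config, path) {
  stopifnot(inherits(config, "kai_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname kai_save_config
#' @export
kai_load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- x$profile
  x$profile <- NULL
  known <- names(.kai_paper_profile())
  unknown <- setdiff(names(x), known)
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  int_fields <- c("n_walkers", "anneal_steps", "sample_steps", "extra_steps",
                  "select_pool", "select_k", "thin", "post_window",
                  "max_generations", "powell_maxit", "evidence_stage_steps",
                  "evidence_use_last")
  for (f in intersect(int_fields, names(x))) x[[f]] <- as.integer(x[[f]])
  do.call(kai_config, c(list(profile = profile), x))
}
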