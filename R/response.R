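# Steady-state stimulus-response analysis: %CP as a function of [KaiA] at
# fixed %ATP, ECx shape metrics (EC10 = threshold measure, EC90 - EC10 =
# switch measure), and the phenomenological substrate-competition curve.

#' Steady-state stimulus-response curve
#'
#' Simulates the phosphorylation reaction to `eval_time` hours at each
#' KaiA concentration on the grid and records the phosphoform percentages
#' at that near-steady-state time. A point is flagged as unsettled when
#' the total phosphorylation still moves faster than `settle_tol` percent
#' per hour at the end.
#'
#' @param params A `kai_params`.
#' @param pct_ATP Solution \%ATP for the whole curve.
#' @param kaiA_grid Strictly increasing KaiA concentrations (monomer, uM);
#'   default 40 log-spaced points on \[0.01, 10\] uM.
#' @param eval_time Evaluation time (hours); 24 h mirrors the steady-state
#'   determination time of the corresponding experiments.
#' @param kaiC_uM Total KaiC (uM).
#' @param settle_tol Settledness threshold, percent per hour.
#' @return A `kai_response_curve`: data frame with `kaiA_uM`, `pct_U/T/S/D`,
#'   `pct_CP`, `settled`; attributes `pct_ATP` and `eval_time`.
#' @export
kai_steady_state_response <- function(params, pct_ATP = 100,
                                      kaiA_grid = NULL, eval_time = 24,
                                      kaiC_uM = 3.5, settle_tol = 0.1) {
  if (is.null(kaiA_grid)) {
    kaiA_grid <- 10^seq(log10(0.01), log10(10), length.out = 40)
  }
  if (is.unsorted(kaiA_grid, strictly = TRUE)) {
    stop("kaiA_grid must be strictly increasing")
  }
  rows <- lapply(kaiA_grid, function(a) {
    cond <- kai_condition(kaiA_uM = a, pct_ATP = pct_ATP, kaiC_uM = kaiC_uM,
                          duration_h = eval_time)
    tr <- kai_simulate(params, cond,
                       t_grid = c(0, eval_time - 1, eval_time))
    if (is.null(tr)) return(NULL)
    ph <- kai_observables(tr)$phosphoforms
    n <- nrow(ph)
    slope <- abs(ph$pct_CP[n] - ph$pct_CP[n - 1]) /
      (ph$time_h[n] - ph$time_h[n - 1])
    data.frame(kaiA_uM = a, pct_U = ph$pct_U[n], pct_T = ph$pct_T[n],
               pct_S = ph$pct_S[n], pct_D = ph$pct_D[n],
               pct_CP = ph$pct_CP[n], settled = slope < settle_tol)
  })
  if (any(vapply(rows, is.null, logical(1)))) {
    stop("integration failed at one or more grid points")
  }
  out <- do.call(rbind, rows)
  attr(out, "pct_ATP") <- pct_ATP
  attr(out, "eval_time") <- eval_time
  class(out) <- c("kai_response_curve", "data.frame")
  out
}

#' ECx of a stimulus-response curve
#'
#' The stimulus level at which the response first reaches x\% of the
#' saturation response above baseline. Saturation is the response at the
#' top of the grid after plateau detection (relative slope below 1\% per
#' decade of stimulus); baseline is the response at zero stimulus,
#' linearly extrapolated from the lowest grid points when the grid does
#' not include zero. The crossing is located by monotone Hermite
#' interpolation and root refinement within the bracketing grid interval.
#'
#' @param curve A `kai_response_curve`, or any data frame with a stimulus
#'   column and a response column.
#' @param x_pct Percentage level x in (0, 100).
#' @param stimulus,response Column names (defaults `kaiA_uM`, `pct_CP`).
#' @param baseline Optional explicit baseline response; default as above.
#' @return ECx in stimulus units, or `NA` (with a warning) when the level
#'   is not attained on the grid.
#' @examples
#' g <- 10^seq(-3, 3, length.out = 400)
#' curve <- data.frame(kaiA_uM = g, pct_CP = g / (1 + g))
#' kai_ec(curve, 10)  # ~ 1/9 for a hyperbola with K = 1
#' @export
kai_ec <- function(curve, x_pct, stimulus = "kaiA_uM",
                   response = "pct_CP", baseline = NULL) {
  s <- curve[[stimulus]]; r <- curve[[response]]
  stopifnot(length(s) >= 4L, !is.unsorted(s, strictly = TRUE))
  if (x_pct <= 0 || x_pct >= 100) stop("x_pct must be in (0, 100)")
  n <- length(s)
  # plateau detection: the relative slope at the top of the grid must be
  # below 1% per decade of stimulus for r[n] to count as saturation
  if (s[n - 1L] > 0 && r[n] > 0) {
    slope_dec <- abs(r[n] - r[n - 1L]) /
      (log10(s[n]) - log10(s[n - 1L])) / max(abs(r[n]), 1e-12)
    if (slope_dec > 0.01) {
      warning("curve has not plateaued at the top of the grid; ",
              "treating the last point as saturation")
    }
  }
  sat <- r[n]
  if (is.null(baseline)) {
    baseline <- if (s[1] <= 0) r[1] else
      max(0, r[1] - (r[2] - r[1]) / (s[2] - s[1]) * s[1])
  }
  level <- baseline + (x_pct / 100) * (sat - baseline)
  above <- r >= level
  if (!any(above)) {
    warning("response level not attained on the grid")
    return(NA_real_)
  }
  i <- which(above)[1]
  if (i == 1L) return(s[1])
  fun <- stats::splinefun(s, r, method = "hyman")
  stats::uniroot(function(a) fun(a) - level, c(s[i - 1L], s[i]),
                 tol = .Machine$double.eps^0.5)$root
}

#' Threshold and switch shape measures
#'
#' `EC10` quantifies threshold-like behavior and `EC90 - EC10` switch-like
#' behavior. For reference, a pure hyperbola `[A]/(K + [A])` has
#' `(EC10, EC90 - EC10) = (K/9, 80K/9)`, i.e. a switch-to-threshold ratio
#' of exactly 80; threshold-hyperbolic curves push EC10 up and the ratio
#' down. The hyperbolic reference scale `K` is obtained by least-squares
#' fit of a scaled hyperbola to the curve.
#'
#' @param curve A `kai_response_curve` (or compatible data frame).
#' @inheritParams kai_ec
#' @return List with `EC10`, `EC90`, `switch` (= EC90 - EC10),
#'   `hyperbola_K` (fitted), and the reference pair `hyperbolic_EC10 =
#'   K/9`, `hyperbolic_switch = 80 K/9`.
#' @export
kai_shape_measures <- function(curve, stimulus = "kaiA_uM",
                               response = "pct_CP") {
  ec10 <- kai_ec(curve, 10, stimulus, response)
  ec90 <- kai_ec(curve, 90, stimulus, response)
  s <- curve[[stimulus]]; r <- curve[[response]]
  # matched hyperbolic reference: same baseline and saturation as the
  # curve itself, only the half-saturation scale K is fitted
  base <- min(r)
  amp <- max(r) - base
  k0 <- s[which.min(abs((r - base) - amp / 2))]
  fit <- try(minpack.lm::nlsLM(
    r ~ base + amp * s / (K + s),
    start = list(K = k0), lower = 1e-8,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  K <- if (inherits(fit, "try-error")) NA_real_ else
    unname(stats::coef(fit)["K"])
  list(EC10 = ec10, EC90 = ec90, switch = ec90 - ec10, hyperbola_K = K,
       hyperbolic_EC10 = K / 9, hyperbolic_switch = 80 * K / 9)
}

#' Substrate-competition stimulus-response function
#'
#' The tight-binding-inhibitor ultrasensitivity scheme: a kinase pool
#' `[K]` is titrated against a stoichiometric inhibitor `[I]` with
#' dissociation constant `K2`; the free kinase then drives a hyperbolic
#' response with half-saturation `K1`, amplitude `Pmax` and baseline `b`.
#' The free-kinase concentration solves the binding quadratic
#' `Kf = ([K] - [I] - K2 + sqrt(([K] - [I] - K2)^2 + 4 K2 [K])) / 2`.
#' As `K2 -> 0` this reduces to the right-shifted hyperbola
#' `Pmax ([K]-[I]) / (K1 + [K]-[I]) * H([K]-[I]) + b` (a
#' threshold-hyperbolic stimulus-response function with threshold `[I]`).
#'
#' @param K_conc Kinase (stimulus) concentrations.
#' @param Pmax,I,K1,K2,b Curve parameters, all >= 0.
#' @return Response values (\%).
#' @export
kai_competition_curve <- function(K_conc, Pmax, I, K1, K2, b = 0) {
  if (any(c(Pmax, I, K1, K2, b) < 0) || any(K_conc < 0)) {
    stop("all parameters and stimuli must be non-negative")
  }
  d <- K_conc - I - K2
  Kf <- (d + sqrt(d^2 + 4 * K2 * K_conc)) / 2
  Pmax * Kf / (K1 + Kf) + b
}

#' Threshold-hyperbolic limit of the competition curve
#'
#' The `K2 -> 0` limit: zero response up to the stimulus threshold `[I]`,
#' then a right-shifted hyperbola in `[K] - [I]`.
#' @inheritParams kai_competition_curve
#' @return Response values (\%).
#' @export
kai_threshold_hyperbolic <- function(K_conc, Pmax, I, K1, b = 0) {
  x <- pmax(0, K_conc - I)
  ifelse(K_conc > I, Pmax * x / (K1 + x), 0) + b
}

#' Fit the substrate-competition curve
#'
#' Nonlinear least squares of [kai_competition_curve()] to stimulus-
#' response data, with multi-start fallback, followed by numerical EC50
#' extraction (root of the fitted curve at half of its fitted amplitude
#' above baseline; EC50 is not an explicit parameter of the scheme).
#'
#' @param K_conc Stimulus concentrations (>= 6 points spanning both sides
#'   of the threshold).
#' @param response Measured responses (\%).
#' @param start Optional named list of starting values.
#' @return List with `coef` (Pmax, I, K1, K2, b), `EC50`, `fitted`, and
#'   `converged`.
#' @export
kai_fit_competition <- function(K_conc, response, start = NULL) {
  stopifnot(length(K_conc) == length(response), length(K_conc) >= 6L)
  df <- data.frame(x = K_conc, y = response)
  base0 <- max(min(response), 1e-6)
  amp0 <- max(response) - min(response)
  starts <- list(
    start,
    list(Pmax = amp0, I = stats::median(K_conc) / 2,
         K1 = stats::median(K_conc) / 4, K2 = 0.01, b = base0),
    list(Pmax = amp0, I = 1e-3, K1 = stats::median(K_conc), K2 = 0.1,
         b = base0),
    list(Pmax = amp0, I = max(K_conc) / 4, K1 = max(K_conc) / 20,
         K2 = 1e-3, b = base0))
  starts <- Filter(Negate(is.null), starts)
  best <- NULL
  for (s0 in starts) {
    fit <- try(minpack.lm::nlsLM(
      y ~ kai_competition_curve(x, Pmax, I, K1, K2, b),
      data = df, start = s0,
      lower = rep(0, 5), upper = c(Inf, Inf, Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(coef = NULL, EC50 = NA_real_, fitted = NULL,
                converged = FALSE))
  }
  cf <- stats::coef(best$fit)
  half <- cf["b"] + cf["Pmax"] / 2
  g <- function(k) kai_competition_curve(k, cf["Pmax"], cf["I"], cf["K1"],
                                         cf["K2"], cf["b"]) - half
  upper <- max(K_conc) * 100
  ec50 <- if (g(upper) < 0) NA_real_ else
    stats::uniroot(g, c(0, upper), tol = 1e-10)$root
  list(coef = cf, EC50 = ec50,
       fitted = kai_competition_curve(K_conc, cf["Pmax"], cf["I"],
                                      cf["K1"], cf["K2"], cf["b"]),
       converged = TRUE)
}
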