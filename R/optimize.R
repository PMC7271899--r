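# Derivative-free local optimization by Powell's direction-set method:
# sequential Brent line minimizations along a direction set, replacing the
# direction of largest decrease with the net sweep displacement. As in the
# commonly used modified form, the directions are not guaranteed to stay
# mutually conjugate.

# Bracketing line minimization of g on an adaptively expanded interval.
.line_min <- function(g, g0, step = 1, max_expand = 30L, tol = 1e-10) {
  lo <- -step; hi <- step
  glo <- g(lo); ghi <- g(hi)
  for (i in seq_len(max_expand)) {
    if (is.finite(glo) && glo < g0 && glo <= ghi) {
      hi <- lo; ghi <- glo; lo <- lo * 2; glo <- g(lo)
    } else if (is.finite(ghi) && ghi < g0 && ghi < glo) {
      lo <- hi; glo <- ghi; hi <- hi * 2; ghi <- g(hi)
    } else break
  }
  if (!is.finite(glo)) lo <- lo / 2
  if (!is.finite(ghi)) hi <- hi / 2
  opt <- stats::optimize(g, c(lo, hi), tol = tol)
  cand <- rbind(c(opt$minimum, opt$objective), c(0, g0))
  best <- cand[which.min(cand[, 2]), ]
  list(t = best[1], value = best[2])
}

#' Powell direction-set minimization
#'
#' Minimizes `f` from `x0` without derivatives: each iteration performs a
#' Brent line search along every vector of the direction set (initially
#' the coordinate axes), then replaces the direction of largest single
#' decrease with the overall displacement of the sweep and line-searches
#' along it. Converges on relative function decrease.
#'
#' @param f Objective function (scalar-valued; may return `Inf`/`NA`
#'   outside its domain).
#' @param x0 Starting point with finite `f(x0)`.
#' @param control List: `maxit` (sweeps, default 100), `reltol` (default
#'   1e-10), `step` (initial line-search half-width, default 0.5),
#'   `line_tol` (Brent tolerance, default 1e-8).
#' @return List with `par`, `value`, `counts` (function evaluations) and
#'   `convergence` (0 = converged, 1 = sweep limit reached).
#' @export
kai_powell <- function(f, x0, control = list()) {
  ctl <- utils::modifyList(list(maxit = 100L, reltol = 1e-10, step = 0.5,
                                line_tol = 1e-8), control)
  n <- length(x0)
  n_eval <- 0L
  fw <- function(x) { n_eval <<- n_eval + 1L; v <- f(x)
    if (!is.finite(v)) Inf else v }
  fx <- fw(x0)
  if (!is.finite(fx)) stop("starting point must have finite objective")
  x <- x0
  dirs <- diag(n)
  convergence <- 1L
  for (iter in seq_len(ctl$maxit)) {
    f_start <- fx
    x_start <- x
    dec <- numeric(n)
    for (i in seq_len(n)) {
      d <- dirs[, i]
      g <- function(t) fw(x + t * d)
      lm <- .line_min(g, fx, step = ctl$step, tol = ctl$line_tol)
      dec[i] <- fx - lm$value
      x <- x + lm$t * d
      fx <- lm$value
    }
    disp <- x - x_start
    if (sqrt(sum(disp^2)) > 0) {
      g <- function(t) fw(x + t * disp)
      lm <- .line_min(g, fx, step = 1, tol = ctl$line_tol)
      x <- x + lm$t * disp
      fx <- lm$value
      i_max <- which.max(dec)
      dirs[, i_max] <- disp / sqrt(sum(disp^2))
    }
    if (f_start - fx <= ctl$reltol * (abs(f_start) + abs(fx)) / 2 + 1e-300) {
      convergence <- 0L
      break
    }
  }
  list(par = x, value = fx, counts = n_eval, convergence = convergence)
}

#' Local optimization of a log-posterior
#'
#' Thin maximization wrapper around [kai_powell()]: runs the direction-set
#' minimizer on the negated log-posterior and guarantees the returned
#' point is never worse than the start.
#'
#' @param logpost_fn Log-posterior function of a coordinate vector.
#' @param start Starting coordinates with finite log-posterior.
#' @param control Passed to [kai_powell()].
#' @return List with `par` and `log_posterior`.
#' @export
kai_local_optimize <- function(logpost_fn, start, control = list()) {
  lp0 <- logpost_fn(start)
  if (!is.finite(lp0)) stop("start must have finite log-posterior")
  res <- kai_powell(function(x) -logpost_fn(x), start, control)
  if (-res$value >= lp0) {
    list(par = res$par, log_posterior = -res$value)
  } else {
    list(par = start, log_posterior = lp0)
  }
}
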