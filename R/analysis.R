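#' Hyperbolic-tangent dose-response function
#'
#' `f(x) = (a / 2) * (tanh(b * (x - c)) + 1)`: a sigmoid rising from 0
#' to the maximum response `a`, with inflection point (half-maximal
#' response) at `x = c` and steepness (sigmoidality) `b`. Large `b`
#' means switch-like; small `b` degrades towards a hyperbolic-looking
#' quasi-linear response over the observed range.
#'
#' @param x Stimulus value(s).
#' @param a Maximum response (`a > 0`).
#' @param b Sigmoidality (1 / stimulus units, `b > 0` for an increasing
#'   response).
#' @param c Inflection point (stimulus units).
#' @return `f(x)`, same length as `x`.
#' @export
#' @examples
#' tanh_response(0.14, a = 0.2, b = 12, c = 0.14)  # a/2 = 0.1
tanh_response <- function(x, a, b, c) {
  a / 2 * (tanh(b * (x - c)) + 1)
}

#' Construct a dose-response curve
#'
#' @param signal Strictly increasing stimulus vector (kphr for
#'   simulations, stressor concentration for experimental data).
#' @param response Matching response vector (RsbS-P fraction or reporter
#'   activity).
#' @param signal_label,response_label Axis labels / units, carried along.
#' @return Object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(signal, response, signal_label = "signal",
                                response_label = "response") {
  stopifnot(is.numeric(signal), is.numeric(response),
            length(signal) == length(response), length(signal) >= 2,
            !anyNA(signal), !anyNA(response))
  if (is.unsorted(signal, strictly = TRUE)) {
    stop("signal must be strictly increasing")
  }
  structure(list(signal = signal, response = response,
                 signal_label = signal_label,
                 response_label = response_label),
            class = "dose_response_curve")
}

#' @export
as.data.frame.dose_response_curve <- function(x, ...) {
  data.frame(signal = x$signal, response = x$response)
}

#' Coerce a simulated dose-response sweep to a curve
#'
#' @param x A [dose_response()] result.
#' @param response Which column to treat as the response.
#' @return A `dose_response_curve`.
#' @export
as_dose_response_curve <- function(x, response = "mean_S_P") {
  stopifnot(inherits(x, "dose_response"))
  dose_response_curve(x$kphr, x[[response]], signal_label = "kphr",
                      response_label = response)
}

#' Fit the tanh response function to a dose-response curve
#'
#' Least-squares fit of [tanh_response()] by deterministic multi-start
#' bounded quasi-Newton minimisation: a fixed grid of initial guesses
#' spanning the signal range (inflection candidates at the signal
#' quantiles, steepness candidates spread over four orders of
#' magnitude), best residual wins, ties broken by first start. Bounds
#' enforce `a > 0`, `b > 0` and `c` within the signal range.
#'
#' @param curve A `dose_response_curve` (or [dose_response()] sweep)
#'   with at least 4 points spanning low and high response.
#' @return Object of class `tanh_fit`: coefficients `a`, `b`, `c`,
#'   residual norm, fitted values and the data.
#' @export
#' @examples
#' x <- seq(0, 1, length.out = 25)
#' crv <- dose_response_curve(x, tanh_response(x, 0.2, 12, 0.14))
#' coef(fit_tanh(crv))
fit_tanh <- function(curve) {
  if (inherits(curve, "dose_response")) {
    curve <- as_dose_response_curve(curve)
  }
  stopifnot(inherits(curve, "dose_response_curve"))
  x <- curve$signal
  y <- curve$response
  if (length(x) < 4) stop("need at least 4 points to fit the tanh response")
  if (stats::sd(y) < 1e-12) stop("response is flat; tanh fit is degenerate")
  if (stats::cor(x, y, method = "spearman") < 0) {
    stop("response decreases with signal; the tanh model requires b > 0")
  }
  sse <- function(p) {
    r <- y - tanh_response(x, p[1], p[2], p[3])
    sum(r * r)
  }
  rng <- diff(range(x))
  starts <- expand.grid(
    a = max(y) * c(1, 1.25),
    b = c(0.3, 1, 3, 10, 30, 100) / rng,
    c = stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  )
  lower <- c(1e-10, 1e-10, min(x))
  upper <- c(Inf, Inf, max(x))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    f <- tryCatch(
      stats::nlminb(as.numeric(starts[k, ]), sse, lower = lower,
                    upper = upper,
                    control = list(rel.tol = 1e-12, iter.max = 500)),
      error = function(e) NULL
    )
    if (is.null(f)) next
    if (is.null(best) || f$objective < best$objective - 1e-15) best <- f
  }
  if (is.null(best)) stop("tanh fit failed to converge from every start")
  co <- c(a = best$par[1], b = best$par[2], c = best$par[3])
  structure(list(coefficients = co,
                 residual_norm = sqrt(best$objective),
                 fitted = tanh_response(x, co["a"], co["b"], co["c"]),
                 curve = curve),
            class = "tanh_fit")
}

#' @export
print.tanh_fit <- function(x, ...) {
  co <- x$coefficients
  cat("Tanh dose-response fit: f(x) = (a/2) (tanh(b (x - c)) + 1)\n")
  cat(sprintf("  a = %.4g (max response)   b = %.4g (sigmoidality)   c = %.4g (inflection)\n",
              co["a"], co["b"], co["c"]))
  cat(sprintf("  residual norm = %.3g over %d points\n",
              x$residual_norm, length(x$fitted)))
  invisible(x)
}

#' @export
coef.tanh_fit <- function(object, ...) object$coefficients

#' @export
residuals.tanh_fit <- function(object, ...) {
  object$curve$response - object$fitted
}

#' @export
predict.tanh_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$curve$signal else newdata
  co <- object$coefficients
  tanh_response(x, co["a"], co["b"], co["c"])
}

#' @export
plot.tanh_fit <- function(x, ...) {
  crv <- x$curve
  graphics::plot(crv$signal, crv$response, xlab = crv$signal_label,
                 ylab = crv$response_label, ...)
  xs <- seq(min(crv$signal), max(crv$signal), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' @export
summary.tanh_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Normalize a dose-response curve by its fitted parameters
#'
#' Divides the signal by the fitted inflection point `c` and the
#' response by the fitted maximum `a`, mapping every tanh-shaped curve
#' onto a common scale where the half-maximal response (0.5) sits at
#' normalized signal 1. Curves with equal products `b * c` collapse onto
#' the identical normalized curve, which is what makes responses to
#' different stressors (or simulated kphr) directly comparable.
#'
#' @param curve A `dose_response_curve`.
#' @param fit A `tanh_fit` for that curve.
#' @return A normalized `dose_response_curve`.
#' @export
normalize_curve <- function(curve, fit) {
  stopifnot(inherits(curve, "dose_response_curve"),
            inherits(fit, "tanh_fit"))
  co <- coef(fit)
  if (abs(co["a"]) < 1e-12 || abs(co["c"]) < 1e-12) {
    stop("cannot normalize: fitted a or c is zero")
  }
  dose_response_curve(curve$signal / co[["c"]], curve$response / co[["a"]],
                      signal_label = paste0(curve$signal_label, " / c"),
                      response_label = paste0(curve$response_label, " / a"))
}

#' Import an experimental dose-response curve from CSV
#'
#' Expects a two-column numeric CSV (signal, response) with a header
#' row; column names become the curve labels, so digitized reporter-gene
#' measurements in arbitrary units can be compared with simulations
#' after [normalize_curve()].
#'
#' @param path CSV file path.
#' @return A `dose_response_curve`.
#' @export
import_experimental_curve <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) != 2) stop("expected exactly two columns (signal, response)")
  if (nrow(df) < 2) stop("need at least 2 rows")
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("both columns must be numeric")
  }
  dose_response_curve(df[[1]], df[[2]], signal_label = names(df)[1],
                      response_label = names(df)[2])
}

#' Export a tanh fit as JSON
#'
#' Writes `{model, a, b, c, residual}`.
#'
#' @param fit A `tanh_fit`.
#' @param path Output path.
#' @param model Label recorded in the file.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path, model = "unspecified") {
  co <- coef(fit)
  jsonlite::write_json(
    list(model = model, a = co[["a"]], b = co[["b"]], c = co[["c"]],
         residual = fit$residual_norm),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
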