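#' Asymptotic acidity-drop model
#'
#' During ripening, plot mean acidity follows an exponential decay towards a
#' horizontal asymptote,
#'
#' \deqn{A(t) = Asym + (A_0 - Asym)\,e^{-e^{lrc}\,t},}
#'
#' where `t` is time in days relative to the reference date at which the plot
#' reached the acidity ceiling (1.4 g citric acid / 100 g juice by default, so
#' `A0 = 1.4` and `A(0) = A0` exactly), `Asym` is the end-of-ripening
#' asymptote, and `lrc` is the natural log of the per-day rate constant.
#'
#' `asymp_params()` builds a validated parameter triple, `acidity_curve()`
#' evaluates the model, and `acidity_inverse()` solves it for time:
#' \eqn{t = -\log((a - Asym)/(A_0 - Asym)) / e^{lrc}} for
#' \eqn{Asym < a \le A_0}. The two are exact inverses on their domains.
#'
#' @param Asym horizontal asymptote, g citric acid / 100 g juice.
#' @param A0 acidity at `t = 0` (the centering reference), default 1.4.
#' @param lrc natural log of the rate constant (log 1/day).
#' @return `asymp_params()`: an object of class `asymp_params`;
#'   `acidity_curve()`: acidity values; `acidity_inverse()`: times in days.
#' @examples
#' p <- asymp_params(Asym = 0.55852, lrc = -3.50741)
#' acidity_curve(0, p)               # 1.4
#' acidity_inverse(0.65, p)          # ~74 days after the 1.4 date
#' @export
asymp_params <- function(Asym, A0 = 1.4, lrc) {
  stopifnot(is.numeric(Asym), is.numeric(A0), is.numeric(lrc),
            length(Asym) == 1, length(A0) == 1, length(lrc) == 1)
  if (!is.finite(Asym) || !is.finite(A0) || !is.finite(lrc)) {
    stop("asymp_params requires finite Asym, A0, lrc", call. = FALSE)
  }
  if (Asym >= A0) stop("Asym must lie below A0 (decaying acidity)", call. = FALSE)
  structure(list(Asym = Asym, A0 = A0, lrc = lrc), class = "asymp_params")
}

#' @rdname asymp_params
#' @param t time in days relative to the reference date (may be negative).
#' @param params an `asymp_params` object (or list with `Asym`, `A0`, `lrc`).
#' @export
acidity_curve <- function(t, params) {
  # equivalent to Asym + (A0 - Asym) * exp(-exp(lrc) * t), written so the
  # anchor A(0) = A0 holds exactly in floating point
  params$A0 + (params$A0 - params$Asym) * expm1(-exp(params$lrc) * t)
}

#' @rdname asymp_params
#' @param acidity acidity value(s) to invert, must lie in `(Asym, A0]`.
#' @export
acidity_inverse <- function(acidity, params) {
  if (any(acidity <= params$Asym | acidity > params$A0)) {
    stop(sprintf(
      "acidity must lie in (Asym, A0] = (%.5g, %.5g]",
      params$Asym, params$A0
    ), call. = FALSE)
  }
  -log((acidity - params$Asym) / (params$A0 - params$Asym)) / exp(params$lrc)
}

#' @export
print.asymp_params <- function(x, ...) {
  cat(sprintf(
    "Asymptotic acidity model: A(t) = %.5f + (%.5f - %.5f) * exp(-exp(%.5f) * t)\n",
    x$Asym, x$A0, x$Asym, x$lrc
  ))
  cat(sprintf("  rate constant exp(lrc) = %.6f / day\n", exp(x$lrc)))
  invisible(x)
}
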