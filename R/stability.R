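#' Construct a protein-decay time course
#'
#' A decay dataset holds OD-normalized immunosignal quantifications from a
#' translation-shutoff experiment: timepoints in minutes (strictly
#' increasing, starting at 0), positive signals (arbitrary units), and
#' optionally the culture growth factor `OD(t)/OD(0)` at each timepoint
#' (`>= 1`, equal to 1 at `t = 0`), used to correct per-biomass signal for
#' dilution by continued growth.
#'
#' @param time timepoints in minutes.
#' @param signal positive signal values.
#' @param growth_factor optional per-timepoint growth factors.
#' @return A `decay_dataset` (a data frame).
#' @export
decay_dataset <- function(time, signal, growth_factor = NULL) {
  if (length(time) != length(signal))
    rf_validation_error("time and signal must have equal length")
  if (time[1] != 0) rf_validation_error("first timepoint must be 0")
  if (any(diff(time) <= 0))
    rf_validation_error("timepoints must be strictly increasing")
  if (any(signal <= 0))
    rf_validation_error("signals must be positive")
  df <- data.frame(time = as.numeric(time), signal = as.numeric(signal))
  if (!is.null(growth_factor)) {
    if (length(growth_factor) != length(time))
      rf_validation_error("growth_factor must match timepoints")
    if (any(growth_factor < 1) || abs(growth_factor[1] - 1) > 1e-9)
      rf_validation_error("growth factors must be >= 1 with growth_factor(0) = 1")
    df$growth_factor <- as.numeric(growth_factor)
  }
  class(df) <- c("decay_dataset", "data.frame")
  df
}

#' Read a decay series from TSV
#'
#' Columns `time_min`, `signal` and optionally `od580` (converted to growth
#' factors by dividing by the value at `t = 0`) or `growth_factor`.
#'
#' @param path file path.
#' @return A [decay_dataset()].
#' @export
read_decay_table <- function(path) {
  df <- rf_read_tsv(path)
  rf_require_cols(df, c("time_min", "signal"), basename(path))
  gf <- NULL
  if ("growth_factor" %in% names(df)) gf <- df$growth_factor
  else if ("od580" %in% names(df)) gf <- df$od580 / df$od580[1]
  decay_dataset(df$time_min, df$signal, gf)
}

#' Write a decay series to TSV
#' @param x a `decay_dataset`.
#' @param path output path.
#' @export
write_decay_table <- function(x, path) {
  out <- data.frame(time_min = x$time, signal = x$signal)
  if (!is.null(x$growth_factor)) out$growth_factor <- x$growth_factor
  rf_write_tsv(out, path)
}

#' Correct a decay series for dilution by growth
#'
#' After translation shutoff the culture keeps growing, so a per-biomass
#' (OD-normalized) signal underestimates the total amount of protein left.
#' Multiplying by the growth factor `OD(t)/OD(0)` converts per-biomass
#' signal to total abundance — the unique correction under which a perfectly
#' stable protein appears constant. The growth factor column is cleared on
#' output so the correction cannot be applied twice.
#'
#' @param data a [decay_dataset()] with growth factors.
#' @return A corrected `decay_dataset` without growth factors.
#' @export
correct_for_dilution <- function(data) {
  if (is.null(data$growth_factor))
    rf_validation_error(paste(
      "no growth data present: supply growth_factor,",
      "or skip the correction explicitly by fitting the raw series"))
  decay_dataset(data$time, data$signal * data$growth_factor)
}

#' Fit a single-exponential decay and report the half-life
#'
#' Fits `signal(t) = A * exp(-k t)`. The default fit is linear regression of
#' `log(signal)` on time (the standard approach for single-exponential blot
#' quantifications); `method = "nls"` performs the direct nonlinear
#' least-squares fit, started from the log-linear estimates. If the data
#' still carry growth factors the series is growth-corrected first. A
#' negative fitted rate (signal increasing) is clamped to `k = 0` with a
#' warning; rates below `1e-12`/min are reported as half-life `Inf`.
#'
#' @param data a [decay_dataset()].
#' @param method `"log-linear"` (default) or `"nls"`.
#' @return A `decay_fit` with components `rate` (per minute), `half_life`
#'   (minutes), `amplitude`, `rss` (residual sum of squares on the signal
#'   scale) and the fitted data.
#' @export
fit_half_life <- function(data, method = c("log-linear", "nls")) {
  method <- match.arg(method)
  if (!is.null(data$growth_factor)) data <- correct_for_dilution(data)
  if (nrow(data) < 3)
    rf_validation_error("need at least 3 timepoints to fit a decay")
  if (method == "log-linear") {
    if (any(data$signal <= 0))
      rf_validation_error(
        "non-positive signal: log-linear fit impossible, use method = 'nls'")
    fit <- stats::lm(log(data$signal) ~ data$time)
    k <- -unname(stats::coef(fit)[2])
    A <- exp(unname(stats::coef(fit)[1]))
  } else {
    lf <- stats::lm(log(pmax(data$signal, 1e-12)) ~ data$time)
    st <- list(A = exp(unname(stats::coef(lf)[1])),
               k = max(-unname(stats::coef(lf)[2]), 1e-6))
    # Levenberg-Marquardt: stable on zero-residual (noiseless) series where
    # Gauss-Newton nls fails
    nfit <- minpack.lm::nlsLM(signal ~ A * exp(-k * time), data = data,
                              start = st)
    cf <- stats::coef(nfit)
    A <- unname(cf["A"]); k <- unname(cf["k"])
  }
  if (k < 0) {
    warning("fitted rate is negative (signal increases); reporting k = 0")
    k <- 0
  }
  half_life <- if (k < 1e-12) Inf else log(2) / k
  fitted <- A * exp(-k * data$time)
  structure(list(rate = k, half_life = half_life, amplitude = A,
                 rss = sum((data$signal - fitted)^2),
                 method = method, data = data),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("single-exponential decay fit (%s)\n", x$method))
  cat(sprintf("  amplitude: %.4g\n  rate k: %.4g /min\n", x$amplitude, x$rate))
  cat(sprintf("  half-life: %s\n",
              if (is.infinite(x$half_life)) "Inf (stable)"
              else sprintf("%.2f min", x$half_life)))
  cat(sprintf("  RSS: %.4g\n", x$rss))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(amplitude = object$amplitude, rate = object$rate,
    half_life = object$half_life)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time
       else if (is.data.frame(newdata)) newdata$time else newdata
  object$amplitude * exp(-object$rate * t)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$signal - predict(object)
}

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$data$time, x$data$signal, xlab = "time (min)",
       ylab = "signal (a.u.)", log = "y", ...)
  tt <- seq(min(x$data$time), max(x$data$time), length.out = 100)
  graphics::lines(tt, x$amplitude * exp(-x$rate * tt))
  invisible(x)
}

#' Percentage of signal remaining at a timepoint
#'
#' `100 * corrected_signal(t) / corrected_signal(0)`. If `data` is a list of
#' decay series (replicates), the across-replicate mean and standard
#' deviation are returned. `t` must be an observed timepoint unless
#' `interpolate = TRUE`, in which case linear interpolation is used (with a
#' warning flag in the result).
#'
#' @param data a [decay_dataset()] or list of them.
#' @param t timepoint in minutes.
#' @param interpolate allow linear interpolation between timepoints?
#' @return For a single series, the percentage; for a list, a named vector
#'   `c(mean, sd)` with the per-series values in `attr(, "values")`.
#' @export
percent_remaining <- function(data, t, interpolate = FALSE) {
  if (is.list(data) && !is.data.frame(data)) {
    vals <- vapply(data, percent_remaining, 0, t = t,
                   interpolate = interpolate)
    out <- c(mean = mean(vals), sd = stats::sd(vals))
    attr(out, "values") <- vals
    return(out)
  }
  if (!is.null(data$growth_factor)) data <- correct_for_dilution(data)
  if (t < data$time[1])
    rf_validation_error("t is before the first timepoint")
  i <- match(t, data$time)
  if (is.na(i)) {
    if (!interpolate)
      rf_validation_error(sprintf(
        "t = %g is not an observed timepoint (set interpolate = TRUE)", t))
    if (t > max(data$time))
      rf_validation_error("t is beyond the last timepoint")
    s <- stats::approx(data$time, data$signal, xout = t)$y
  } else {
    s <- data$signal[i]
  }
  100 * s / data$signal[1]
}
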