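#' Construct an oxidation curve
#'
#' One well's fluorescence time series: the decay of reduced phenazine
#' (which is fluorescent) reports oxidation. Rows with missing values are
#' dropped with a warning giving the count.
#'
#' @param time_h Strictly increasing times in hours, length >= 3.
#' @param fluorescence Non-negative fluorescence, same length.
#' @return An `oxidation_curve` tibble with columns `time_h`, `fluorescence`.
#' @export
oxidation_curve <- function(time_h, fluorescence) {
  stopifnot(is.numeric(time_h), is.numeric(fluorescence),
            length(time_h) == length(fluorescence))
  keep <- is.finite(time_h) & is.finite(fluorescence)
  if (any(!keep)) {
    warning(sum(!keep), " time point(s) with missing values dropped", call. = FALSE)
    time_h <- time_h[keep]; fluorescence <- fluorescence[keep]
  }
  if (length(time_h) < 3L) stop("a curve needs at least 3 time points", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("`time_h` must be strictly increasing", call. = FALSE)
  }
  if (any(fluorescence < 0)) stop("`fluorescence` must be >= 0", call. = FALSE)
  out <- tibble(time_h = time_h, fluorescence = fluorescence)
  class(out) <- c("oxidation_curve", class(out))
  out
}

# tricube weight on scaled distance in [0, 1]
tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w[!is.finite(w)] <- 0
  w
}

# weighted straight-line fit; returns intercept value at x0 and slope
wls_line <- function(x, y, w, x0) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= .Machine$double.eps * max(1, sum(w * x^2))) {
    return(c(value = yb, slope = 0))
  }
  b <- sum(w * (x - xb) * (y - yb)) / sxx
  c(value = yb + b * (x0 - xb), slope = b)
}

#' LOWESS smoothing with local slopes
#'
#' Locally weighted scatterplot smoothing of a fluorescence decay curve: at
#' each observed time point a straight line is fit by weighted least squares
#' over the `ceiling(fraction * N)` nearest neighbors in time (ties broken
#' toward earlier time points), with tricube weights on distance scaled by
#' the span of the neighbor window. The smoothed value is the local fit
#' evaluated at the point and the local slope is retained -- the slope is
#' the derivative estimate used downstream, which is why this fit is done
#' in-package rather than through a smoother that discards it. Optional
#' robustness iterations down-weight large residuals by the standard
#' bisquare rule.
#'
#' @param curve An [oxidation_curve()], or anything with `time_h` and
#'   `fluorescence` columns.
#' @param fraction Window fraction in (0, 1]; the sliding window holds
#'   `ceiling(fraction * N)` points and must hold at least 2.
#' @param iterations Number of robustness passes (>= 0, default 0).
#' @return A `lowess_fit`: list with `time_h`, `smoothed`, `slope`,
#'   `fraction`, `iterations`, `k` (window size).
#' @export
lowess_smooth <- function(curve, fraction = 0.05, iterations = 0L) {
  x <- curve$time_h
  y <- curve$fluorescence
  n <- length(x)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  k <- as.integer(ceiling(fraction * n))
  if (k < 2L) {
    stop("window of ", k, " point(s) is too small: need ceiling(fraction * N) >= 2",
         call. = FALSE)
  }
  if (iterations < 0) stop("`iterations` must be >= 0", call. = FALSE)
  rob <- rep(1, n)
  for (pass in seq_len(iterations + 1L)) {
    fitted <- numeric(n)
    slope <- numeric(n)
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      nb <- order(d, x)[seq_len(k)]   # ties toward earlier times
      dmax <- max(d[nb])
      w <- if (dmax > 0) tricube(d[nb] / dmax) else rep(1, k)
      w <- w * rob[nb]
      if (sum(w > 0) < 2L || length(unique(x[nb][w > 0])) < 2L) {
        w <- rob[nb]
        if (sum(w > 0) < 2L) w <- rep(1, k)
      }
      fs <- wls_line(x[nb], y[nb], w, x[i])
      fitted[i] <- fs[["value"]]
      slope[i] <- fs[["slope"]]
    }
    if (pass <= iterations) {
      res <- y - fitted
      s <- median(abs(res))
      rob <- if (s > 0) {
        u <- res / (6 * s)
        ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      } else rep(1, n)
    }
  }
  structure(list(time_h = x, smoothed = fitted, slope = slope,
                 fraction = fraction, iterations = as.integer(iterations), k = k),
            class = "lowess_fit")
}

#' @export
print.lowess_fit <- function(x, ...) {
  cat(sprintf("<lowess_fit> %d points, fraction %.3g (window %d), %d robustness pass(es)\n",
              length(x$time_h), x$fraction, x$k, x$iterations))
  invisible(x)
}

#' Oxidation rate series from a smoothed fit
#'
#' The oxidation rate is the negated local slope of the smoothed
#' fluorescence: positive while fluorescence decays (phenazine being
#' oxidized), negative if the well is accumulating reduced phenazine.
#'
#' @param fit A [lowess_smooth()] result.
#' @param finite_diff Use centered finite differences of the smoothed values
#'   instead of the local-fit slopes (cross-checking mode).
#' @return Tibble with `time_h`, `rate`.
#' @export
oxidation_rate_series <- function(fit, finite_diff = FALSE) {
  stopifnot(inherits(fit, "lowess_fit"))
  if (finite_diff) {
    t <- fit$time_h; s <- fit$smoothed; n <- length(t)
    g <- numeric(n)
    g[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    g[1] <- (s[2] - s[1]) / (t[2] - t[1])
    g[n] <- (s[n] - s[n - 1]) / (t[n] - t[n - 1])
    return(tibble(time_h = t, rate = -g))
  }
  tibble(time_h = fit$time_h, rate = -fit$slope)
}
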