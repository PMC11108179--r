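#' Extract oxidation kinetics metrics from one curve
#'
#' The analysis pipeline applied to every well: LOWESS-smooth the
#' fluorescence decay, take the maximum oxidation rate (negated local slope)
#' and its time, and find the first time the smoothed fraction-oxidized
#' `f(t) = 1 - smoothed(t) / baseline` crosses the threshold (50% by
#' default), linearly interpolated between the bracketing grid points. The
#' baseline (the 100%-reduced anchor) defaults to the mean of the first
#' `baseline_points` smoothed values so that a noisy first read does not set
#' the anchor; `"first"` and `"max"` anchors are available for comparison.
#' Wells that never cross the threshold within the record report a
#' not-detected `t_half` (`NA` with `detected = FALSE`) -- never the assay
#' end time. Wells whose fluorescence rises (net phenazine reduction)
#' naturally report a negative maximum oxidation rate and not-detected.
#'
#' @param curve An [oxidation_curve()].
#' @param fraction LOWESS window fraction (default 0.05).
#' @param threshold Oxidized fraction defining `t_half`, in (0, 1).
#' @param baseline_points Number of early smoothed points averaged into the
#'   baseline (>= 1).
#' @param baseline_anchor `"first_k_mean"` (default), `"first"` or `"max"`.
#' @param iterations Robustness iterations passed to [lowess_smooth()].
#' @return One-row tibble: `max_rate` (fluorescence units/h, may be
#'   negative), `t_at_max` (h), `t_half` (h or `NA`), `detected`, `baseline`,
#'   `fraction`.
#' @export
extract_metrics <- function(curve, fraction = 0.05, threshold = 0.5,
                            baseline_points = 3L,
                            baseline_anchor = c("first_k_mean", "first", "max"),
                            iterations = 0L) {
  baseline_anchor <- match.arg(baseline_anchor)
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)", call. = FALSE)
  if (baseline_points < 1L) stop("`baseline_points` must be >= 1", call. = FALSE)
  fit <- lowess_smooth(curve, fraction = fraction, iterations = iterations)
  s <- fit$smoothed
  baseline <- switch(baseline_anchor,
    first_k_mean = mean(head(s, baseline_points)),
    first = s[1],
    max = max(s))
  if (!is.finite(baseline) || baseline <= 0) {
    stop("unusable curve: baseline is ", signif(baseline, 3),
         " (must be positive)", call. = FALSE)
  }
  rate <- -fit$slope
  i_max <- which.max(rate)
  f_ox <- 1 - s / baseline
  cross <- which(f_ox >= threshold)
  if (length(cross)) {
    j <- cross[1]
    if (j == 1L) {
      t_half <- fit$time_h[1]
    } else {
      f0 <- f_ox[j - 1L]; f1 <- f_ox[j]
      t_half <- fit$time_h[j - 1L] +
        (threshold - f0) / (f1 - f0) * (fit$time_h[j] - fit$time_h[j - 1L])
    }
    detected <- TRUE
  } else {
    t_half <- NA_real_
    detected <- FALSE
  }
  tibble(max_rate = rate[i_max], t_at_max = fit$time_h[i_max],
         t_half = t_half, detected = detected,
         baseline = baseline, fraction = fraction)
}

#' Scan the LOWESS window fraction
#'
#' Re-extracts the kinetics metrics over a grid of window fractions, the
#' sensitivity analysis used to pick a stable minimal window. Per-fraction
#' failures (e.g. windows below 2 points) are recorded as row-level flags
#' rather than aborting the scan.
#'
#' @param curve An [oxidation_curve()].
#' @param fractions Numeric vector of window fractions in (0, 1].
#' @param ... Passed to [extract_metrics()].
#' @return Tibble: `fraction`, `max_rate`, `t_at_max`, `t_half`, `detected`,
#'   `ok`, `error`.
#' @export
scan_fraction <- function(curve, fractions = seq(0.02, 0.5, by = 0.02), ...) {
  rows <- lapply(fractions, function(f) {
    res <- tryCatch(extract_metrics(curve, fraction = f, ...),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      tibble(fraction = f, max_rate = NA_real_, t_at_max = NA_real_,
             t_half = NA_real_, detected = NA, ok = FALSE, error = res)
    } else {
      tibble(fraction = f, max_rate = res$max_rate, t_at_max = res$t_at_max,
             t_half = res$t_half, detected = res$detected, ok = TRUE,
             error = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

#' Per-strain replicate summary of kinetics metrics
#'
#' Computes metrics for every well of a plate, then collapses technical
#' replicates into their biological replicate -- the biological replicate is
#' the statistical unit carried into group comparisons. Technical collapse
#' either averages the per-well metrics (`"metrics"`, default) or averages
#' the technical fluorescence curves before fitting (`"curves"`). A
#' biological replicate's `t_half` is `NA` unless all its technical wells
#' detected the threshold. Wells with unusable baselines are excluded with
#' a message giving the count.
#'
#' @param plate A plate table: columns `time_h`, `well`, `strain`,
#'   `replicate_id`, `replicate_type`, `fluorescence`.
#' @param fraction,threshold,... Passed to [extract_metrics()].
#' @param tech_average `"metrics"` or `"curves"`.
#' @return Tibble with one row per (strain, biological replicate):
#'   `strain`, `replicate_id`, `replicate_type`, `max_rate`, `t_at_max`,
#'   `t_half`, `detected`, `n_tech`.
#' @export
summarize_replicates <- function(plate, fraction = 0.05, threshold = 0.5,
                                 tech_average = c("metrics", "curves"), ...) {
  tech_average <- match.arg(tech_average)
  check_plate_columns(plate)
  dropped <- 0L
  groups <- split(as.data.frame(plate),
                  list(plate$strain, plate$replicate_id), drop = TRUE)
  rows <- lapply(groups, function(g) {
    wells <- split(g, g$well)
    if (tech_average == "curves") {
      tmat <- vapply(wells, function(w) w$fluorescence, numeric(nrow(wells[[1]])))
      avg <- oxidation_curve(wells[[1]]$time_h, rowMeans(tmat))
      met <- tryCatch(
        extract_metrics(avg, fraction = fraction, threshold = threshold, ...),
        error = function(e) NULL)
      if (is.null(met)) { dropped <<- dropped + length(wells); return(NULL) }
      met$n_tech <- length(wells)
    } else {
      per_well <- lapply(wells, function(w) {
        tryCatch(extract_metrics(oxidation_curve(w$time_h, w$fluorescence),
                                 fraction = fraction, threshold = threshold, ...),
                 error = function(e) NULL)
      })
      bad <- vapply(per_well, is.null, logical(1))
      dropped <<- dropped + sum(bad)
      per_well <- per_well[!bad]
      if (!length(per_well)) return(NULL)
      mm <- dplyr::bind_rows(per_well)
      met <- tibble(
        max_rate = mean(mm$max_rate),
        t_at_max = mean(mm$t_at_max),
        t_half = if (all(mm$detected)) mean(mm$t_half) else NA_real_,
        detected = all(mm$detected),
        baseline = mean(mm$baseline),
        fraction = fraction,
        n_tech = nrow(mm))
    }
    met$strain <- g$strain[1]
    met$replicate_id <- g$replicate_id[1]
    met$replicate_type <- g$replicate_type[1]
    met
  })
  if (dropped > 0) {
    message(dropped, " well(s) excluded for unusable baselines")
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$strain, out$replicate_id), ]
  out[, c("strain", "replicate_id", "replicate_type", "max_rate",
          "t_at_max", "t_half", "detected", "n_tech")]
}

#' Integrate a chronoamperometry current trace
#'
#' Trapezoidal integral of a current trace into cumulative charge and
#' phenazine equivalents (two electrons per phenazine). A microamp-hour is
#' 3.6e-3 coulombs. Net-negative charge (reducing current) is permitted and
#' flagged.
#'
#' @param time_h Strictly increasing times (h).
#' @param current_uA Finite currents (uA).
#' @return List: `charge_C`, `pca_mol`, `negative` (TRUE when the net charge
#'   is negative).
#' @export
integrate_current <- function(time_h, current_uA) {
  stopifnot(length(time_h) == length(current_uA), length(time_h) >= 2L)
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("`time_h` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(current_uA))) stop("`current_uA` must be finite", call. = FALSE)
  n <- length(time_h)
  uA_h <- sum(diff(time_h) * (current_uA[-1] + current_uA[-n]) / 2)
  charge <- uA_h * 3.6e-3
  neg <- charge < 0
  if (neg) warning("net negative charge: trace is net reducing", call. = FALSE)
  list(charge_C = charge, pca_mol = charge / (2 * FARADAY), negative = neg)
}

check_plate_columns <- function(plate) {
  need <- c("time_h", "well", "strain", "replicate_id", "replicate_type",
            "fluorescence")
  miss <- setdiff(need, names(plate))
  if (length(miss)) {
    stop("plate table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
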