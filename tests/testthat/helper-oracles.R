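# Brute-force per-point weighted least squares oracle for the LOWESS fit.
# Independent of the package implementation: neighbor selection and weights
# are re-derived here and each local fit goes through lm().
lowess_oracle <- function(time_h, fluorescence, fraction) {
  n <- length(time_h)
  k <- ceiling(fraction * n)
  sm <- numeric(n)
  sl <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(time_h - time_h[i])
    nb <- order(d, time_h)[seq_len(k)]
    dmax <- max(d[nb])
    w <- if (dmax > 0) (1 - pmin(d[nb] / dmax, 1)^3)^3 else rep(1, k)
    if (sum(w > 0) < 2 || length(unique(time_h[nb][w > 0])) < 2) w <- rep(1, k)
    df <- data.frame(x = time_h[nb], y = fluorescence[nb])
    fit <- stats::lm(y ~ x, data = df, weights = w)
    sm[i] <- unname(predict(fit, newdata = data.frame(x = time_h[i])))
    sl[i] <- unname(coef(fit)[2])
  }
  list(smoothed = sm, slope = sl)
}

# Hand-coded Welch two-sided t-test oracle.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}

# Shared recovery harness: fit every well of a generated plate and compare
# with its ground truth. Returns one row per well.
recovery_table <- function(gen, fraction = 0.05, step = 0.25) {
  wells <- split(as.data.frame(gen$plate), gen$plate$well)
  rows <- lapply(wells, function(w) {
    met <- extract_metrics(oxidation_curve(w$time_h, w$fluorescence),
                           fraction = fraction)
    tru <- gen$truth[gen$truth$strain == w$strain[1] &
                       gen$truth$replicate_id == w$replicate_id[1], ]
    data.frame(
      strain = w$strain[1],
      rate_rel_err = abs(met$max_rate - tru$max_rate) / abs(tru$max_rate),
      t_half_err = if (is.finite(met$t_half) && is.finite(tru$t_half))
        abs(met$t_half - tru$t_half) else Inf,
      both_detected = met$detected == tru$detected
    )
  })
  do.call(rbind, rows)
}

recovery_design <- function() {
  list(plate_entry("fast", curve_params()),
       plate_entry("slow", curve_params(lag_h = 8, k_fast = 0.08, k_slow = 0.02)))
}
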