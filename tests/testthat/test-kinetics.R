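test_that("local linear fits are exact on straight lines for any window", {
  t <- seq(0, 48, 0.5)
  y <- 500 - 10 * t
  for (f in c(0.05, 0.3, 1)) {
    fit <- lowess_smooth(oxidation_curve(t, y), fraction = f)
    expect_equal(fit$smoothed, y, tolerance = 1e-9)
    expect_equal(fit$slope, rep(-10, length(t)), tolerance = 1e-9)
    rate <- oxidation_rate_series(fit)
    expect_equal(rate$rate, rep(10, length(t)), tolerance = 1e-9)
  }
  # constant input: zero slopes
  fitc <- lowess_smooth(oxidation_curve(t, rep(7, length(t))), fraction = 0.1)
  expect_equal(fitc$smoothed, rep(7, length(t)), tolerance = 1e-12)
  expect_equal(fitc$slope, rep(0, length(t)), tolerance = 1e-12)
})

test_that("smoother matches the brute-force weighted least squares oracle", {
  withr::with_seed(202, {
    for (rep in 1:6) {
      n <- sample(5:50, 1)
      t <- sort(runif(n, 0, 48))
      y <- 1000 * exp(-0.1 * t) + rnorm(n, 0, 5)
      for (f in c(0.2, 0.5, 1)) {
        if (ceiling(f * n) < 2) next
        fit <- lowess_smooth(oxidation_curve(t, abs(y)), fraction = f)
        ora <- lowess_oracle(t, abs(y), f)
        expect_equal(fit$smoothed, ora$smoothed, tolerance = 1e-10)
        expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
      }
    }
  })
  # fraction 1 on quadratic data = one global weighted fit per point
  t <- seq(0, 10, 0.5)
  y <- 100 + (t - 5)^2
  fit <- lowess_smooth(oxidation_curve(t, y), fraction = 1)
  ora <- lowess_oracle(t, y, 1)
  expect_equal(fit$smoothed, ora$smoothed, tolerance = 1e-10)
  expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
})

test_that("window validation rejects out-of-range fractions and tiny windows", {
  cur <- oxidation_curve(seq(0, 10), rep(5, 11))
  expect_error(lowess_smooth(cur, fraction = 0), "fraction")
  expect_error(lowess_smooth(cur, fraction = 1.5), "fraction")
  expect_error(lowess_smooth(cur, fraction = 0.05), "too small")
  expect_error(lowess_smooth(cur, fraction = 0.2, iterations = -1), "iterations")
})

test_that("robustness iterations pull the fit toward the uncontaminated trend", {
  t <- seq(0, 48, 0.25)
  y <- 1000 * exp(-0.08 * t)
  y_spiked <- y
  idx <- seq(20, 180, by = 40)
  y_spiked[idx] <- y_spiked[idx] + 300
  fit0 <- lowess_smooth(oxidation_curve(t, y_spiked), fraction = 0.1, iterations = 0)
  fit2 <- lowess_smooth(oxidation_curve(t, y_spiked), fraction = 0.1, iterations = 2)
  expect_lt(mean(abs(fit2$smoothed - y)), mean(abs(fit0$smoothed - y)))
})

test_that("rate sign convention: decay is positive, rise is negative", {
  t <- seq(0, 20, 0.25)
  rising <- oxidation_curve(t, 100 + 5 * t)
  fit <- lowess_smooth(rising, fraction = 0.2)
  expect_true(all(oxidation_rate_series(fit)$rate < 0))
  met <- extract_metrics(rising, fraction = 0.2)
  expect_lt(met$max_rate, 0)
  expect_false(met$detected)
  expect_true(is.na(met$t_half))
})

test_that("metrics recover closed-form kinetics of noiseless curves", {
  # single exponential from t = 0: t_half = ln 2 / k within one grid step
  p <- curve_params(lag_h = 0, k_fast = 0.1, w_fast = 1, floor_frac = 0,
                    lag_smooth = 0)
  cur <- generate_curve(p, noise = noise_model(0, 0))
  met <- extract_metrics(cur, baseline_anchor = "first")
  expect_lt(abs(met$t_half - log(2) / 0.1), 0.25)
  # biphasic family: peak rate and its position against the analytic truth
  pb <- curve_params()
  curb <- generate_curve(pb, noise = noise_model(0, 0))
  metb <- extract_metrics(curb)
  trub <- curve_truth(pb)
  expect_lt(abs(metb$max_rate - trub$max_rate) / trub$max_rate, 0.02)
  expect_lt(abs(metb$t_at_max - trub$t_at_max), 0.3)
  expect_lt(abs(metb$t_half - trub$t_half), 0.25)
})

test_that("wells never reaching the threshold are not-detected, not coerced", {
  p <- curve_params(floor_frac = 0.7)   # decays to 70% of baseline only
  cur <- generate_curve(p, noise = noise_model(0, 0))
  met <- extract_metrics(cur)
  expect_false(met$detected)
  expect_true(is.na(met$t_half))
  # same curve with a permissive threshold is detected inside the record
  met2 <- extract_metrics(cur, threshold = 0.2)
  expect_true(met2$detected)
  expect_lt(met2$t_half, max(cur$time_h))
})

test_that("metrics are invariant to uniform fluorescence rescaling", {
  cur <- generate_curve(curve_params(), noise = noise_model(0.01, 0, seed = 8L))
  m1 <- extract_metrics(cur)
  m10 <- extract_metrics(oxidation_curve(cur$time_h, 10 * cur$fluorescence))
  expect_equal(m10$t_half, m1$t_half, tolerance = 1e-9)
  expect_equal(m10$max_rate, 10 * m1$max_rate, tolerance = 1e-9)
  expect_equal(m10$baseline, 10 * m1$baseline, tolerance = 1e-9)
})

test_that("unusable baselines raise an error instead of silent metrics", {
  flat0 <- oxidation_curve(seq(0, 10, 0.5), rep(0, 21))
  expect_error(extract_metrics(flat0), "baseline")
  expect_error(extract_metrics(generate_curve(curve_params(), noise = noise_model(0, 0)),
                               threshold = 1.5), "threshold")
})

test_that("fraction scan is consistent, failure-tolerant, and stable on lines", {
  t <- seq(0, 48, 0.25)
  lin <- oxidation_curve(t, 1000 - 12 * t)
  sc <- scan_fraction(lin, c(0.05, 0.1, 0.3, 1))
  expect_true(all(sc$ok))
  expect_equal(sc$max_rate, rep(12, 4), tolerance = 1e-8)
  # single fraction row equals extract_metrics exactly
  cur <- generate_curve(curve_params(), noise = noise_model(0.01, 1, seed = 2L))
  sc1 <- scan_fraction(cur, 0.05)
  met <- extract_metrics(cur, fraction = 0.05)
  expect_equal(sc1$max_rate, met$max_rate)
  expect_equal(sc1$t_half, met$t_half)
  # invalid fraction becomes a flagged row, not an abort
  sc2 <- scan_fraction(cur, c(0.002, 0.05))
  expect_false(sc2$ok[1])
  expect_match(sc2$error[1], "too small")
  expect_true(sc2$ok[2])
})

test_that("smoothing attenuates the peak rate beyond the stability plateau", {
  fracs <- c(0.05, 0.1, 0.2, 0.35, 0.5)
  means <- rowMeans(vapply(1:20, function(s) {
    cur <- generate_curve(curve_params(), noise = noise_model(0.01, 1, seed = s))
    scan_fraction(cur, fracs)$max_rate
  }, numeric(length(fracs))))
  expect_true(all(diff(means) < 0))
})

test_that("replicate summary collapses technical wells onto biological units", {
  des <- list(plate_entry("a", curve_params(), n_bio = 3, n_tech = 3),
              plate_entry("b", curve_params(lag_h = 8, k_fast = 0.08),
                          n_bio = 3, n_tech = 3),
              plate_entry("abiotic", abiotic_params(), n_bio = 3, n_tech = 1,
                          type = "abiotic"))
  g <- generate_plate(des, seed = 21L)
  sm <- summarize_replicates(g$plate)
  expect_identical(nrow(sm[sm$strain %in% c("a", "b"), ]), 6L)
  expect_identical(nrow(sm[sm$strain == "abiotic", ]), 3L)
  expect_true(all(sm$n_tech[sm$strain == "a"] == 3))
  # identical technical wells: biological metric equals the single-well metric
  des0 <- list(plate_entry("s", curve_params(), n_bio = 1, n_tech = 3))
  g0 <- generate_plate(des0, noise = noise_model(0, 0), seed = 1L, bio_cv = 0,
                       lag_sd = 0)
  sm0 <- summarize_replicates(g0$plate)
  w1 <- g0$plate[g0$plate$well == g0$plate$well[1], ]
  met1 <- extract_metrics(oxidation_curve(w1$time_h, w1$fluorescence))
  expect_equal(sm0$max_rate, met1$max_rate)
  expect_equal(sm0$t_half, met1$t_half)
  # curve-averaging mode agrees on noiseless identical replicates
  smc <- summarize_replicates(g0$plate, tech_average = "curves")
  expect_equal(smc$max_rate, met1$max_rate)
})
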