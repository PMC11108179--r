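test_that("curve parameter validation names every offending field", {
  err <- expect_error(curve_params(F0 = -1, k_fast = -2, w_fast = 3))
  expect_match(conditionMessage(err), "F0")
  expect_match(conditionMessage(err), "k_fast")
  expect_match(conditionMessage(err), "w_fast")
})

test_that("inert parameters give a constant curve and deterministic noise draws", {
  p <- curve_params(k_fast = 0, k_slow = 0, floor_frac = 0, lag_smooth = 0)
  cur <- generate_curve(p, noise = noise_model(0, 0))
  expect_equal(cur$fluorescence, rep(1000, nrow(cur)))
  n <- noise_model(0.01, 2, seed = 99L)
  c1 <- generate_curve(curve_params(), noise = n)
  c2 <- generate_curve(curve_params(), noise = n)
  expect_identical(c1$fluorescence, c2$fluorescence)
  c3 <- generate_curve(curve_params(), noise = noise_model(0.01, 2, seed = 100L))
  expect_false(identical(c1$fluorescence, c3$fluorescence))
})

test_that("hard-lag single exponential has the closed-form half-life and peak rate", {
  p <- curve_params(F0 = 800, lag_h = 5, k_fast = 0.3, w_fast = 1,
                    floor_frac = 0, lag_smooth = 0)
  t_half_true <- 5 + log(2) / 0.3
  expect_equal(curve_value(p, t_half_true), 400, tolerance = 1e-10)
  tru <- curve_truth(p)
  expect_equal(tru$t_half, t_half_true, tolerance = 1e-6)
  # analytic maximum of the derivative: k * amplitude, at the lag end
  expect_equal(tru$max_rate, 0.3 * 800, tolerance = 1e-6)
  expect_equal(tru$t_at_max, 5, tolerance = 0.01)
})

test_that("smooth lag transition reduces to the hard lag as the width vanishes", {
  t <- seq(0, 48, 0.25)
  hard <- curve_value(curve_params(lag_smooth = 0), t)
  nearly <- curve_value(curve_params(lag_smooth = 1e-4), t)
  expect_equal(nearly, hard, tolerance = 1e-4)
})

test_that("plate generation counts wells and honors jitter settings", {
  g <- generate_plate(seed = 5L)  # fast + slow (3x3) + abiotic (3x1)
  expect_identical(length(unique(g$plate$well)), 21L)
  expect_identical(nrow(g$truth), 9L)
  expect_setequal(unique(g$plate$replicate_type), c("technical", "abiotic"))
  # zero jitter, zero noise: technical and biological replicates identical
  des <- list(plate_entry("s", curve_params(), n_bio = 2, n_tech = 2))
  g0 <- generate_plate(des, noise = noise_model(0, 0), seed = 1L,
                       bio_cv = 0, lag_sd = 0)
  wells <- split(g0$plate$fluorescence, g0$plate$well)
  for (w in wells[-1]) expect_equal(w, wells[[1]])
  expect_equal(g0$truth$max_rate[1], g0$truth$max_rate[2])
  dup <- list(plate_entry("s", curve_params()), plate_entry("s", curve_params()))
  expect_error(generate_plate(dup), "duplicate strain")
})

test_that("fixed seeds make whole plates reproducible", {
  g1 <- generate_plate(seed = 11L)
  g2 <- generate_plate(seed = 11L)
  expect_identical(g1$plate$fluorescence, g2$plate$fluorescence)
  expect_identical(g1$truth, g2$truth)
})

test_that("metric spread grows with the noise level", {
  p <- curve_params()
  sds <- vapply(c(0.002, 0.01, 0.05), function(cv) {
    rates <- vapply(1:20, function(s) {
      cur <- generate_curve(p, noise = noise_model(cv, 0, seed = s))
      extract_metrics(cur)$max_rate
    }, numeric(1))
    sd(rates)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("mechanistic plate entries carry simulation-derived ground truth", {
  m <- assemble_model(genotype_preset("wildtype"))
  des <- list(plate_entry("wt", m, n_bio = 2, n_tech = 1))
  g <- generate_plate(des, noise = noise_model(0, 0), seed = 3L, bio_cv = 0)
  r <- recovery_table(g)
  # the mechanistic flux peaks right at assay start, where boundary smoothing
  # dilutes the derivative estimate; a looser band than the curve-family
  # harness is appropriate here
  expect_true(all(r$rate_rel_err < 0.10))
  expect_true(all(r$t_half_err < 0.25))
})

test_that("current traces integrate back to the electrons the model moved", {
  m <- assemble_model(genotype_preset("wildtype"), model_params(TEA0 = 100))
  tr <- generate_current_trace(m, seq(0, 24, 0.05))
  ic <- integrate_current(tr$time_h, tr$current_uA)
  expect_equal(ic$charge_C, attr(tr, "charge_C"), tolerance = 1e-3)
  expect_equal(ic$pca_mol, attr(tr, "pca_mol"), tolerance = 1e-3)
  # no phenazine, no current
  m0 <- assemble_model(genotype_preset("wildtype"), model_params(PCA_red0 = 0))
  tr0 <- generate_current_trace(m0, seq(0, 24, 0.1))
  expect_equal(max(abs(tr0$current_uA)), 0)
})

test_that("current trace integration passes the hand-arithmetic and refinement checks", {
  # constant 10 uA for 2 h
  ic <- integrate_current(seq(0, 2, 0.1), rep(10, 21))
  expect_equal(ic$charge_C, 0.072, tolerance = 1e-9)
  expect_equal(ic$pca_mol, 0.072 / (2 * 96485.33212), tolerance = 1e-9)
  expect_lt(abs(ic$pca_mol - 3.731e-7), 2e-10)
  # zero current
  ic0 <- integrate_current(c(0, 1, 2), c(0, 0, 0))
  expect_identical(ic0$charge_C, 0)
  # smooth trace vs its two-fold refinement
  t1 <- seq(0, 2, by = 0.002)
  t2 <- seq(0, 2, by = 0.001)
  f <- function(t) 1 + 0.5 * sin(t)
  q1 <- integrate_current(t1, f(t1))$charge_C
  q2 <- integrate_current(t2, f(t2))$charge_C
  expect_lt(abs(q1 - q2), 1e-9)
  # reducing current is flagged
  expect_warning(icn <- integrate_current(c(0, 1), c(-5, -5)), "net reducing")
  expect_true(icn$negative)
})
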