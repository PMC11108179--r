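null_params <- function(...) {
  args <- utils::modifyList(list(k2 = 0, k1 = 0, k3 = 0), list(...))
  do.call(model_params, args)
}

random_model <- function() {
  g <- genotype_preset("wildtype")
  kos <- sample(c(REDUCTASE_GENES, QUINONE_GENES),
                sample(0:4, 1))
  if (length(kos)) g <- do.call(knockout, c(list(g), as.list(kos)))
  p <- model_params(
    k2 = runif(3, 0.01, 0.5), k1 = runif(7, 0, 0.02),
    k3 = 10^runif(1, -8, -6), Vmax = runif(7, 1, 10),
    K_TEA = runif(1, 20, 500), PCA_red0 = runif(1, 50, 200),
    Q_tot = runif(3, 0.1, 1), TEA0 = runif(1, 1e3, 2e4),
    q_red_frac0 = runif(1), lag = sample(c(0, runif(1, 0, 5)), 1))
  acceptor <- sample(c("nitrate", "fumarate", "DMSO", "TMAO"), 1)
  cond <- pregrowth_condition(sample(c("oxic", "hypoxic"), 1))
  assemble_model(g, p, cond, acceptor)
}

test_that("null fluxes leave the phenazine pool constant over 48 h", {
  m <- assemble_model(genotype_preset("wildtype"), null_params())
  tr <- simulate_etc(m)
  expect_equal(tr$PCA_red, rep(100, nrow(tr)), tolerance = 1e-10)
  expect_equal(max(tr$cum_ox), 0, tolerance = 1e-10)
})

test_that("category-3-only model follows the pseudo-first-order closed form", {
  # no cells, large TEA excess: PCA_red(t) = PCA0 * exp(-k3 * TEA0 * t)
  p <- model_params(k3 = 1e-6, TEA0 = 1e6, PCA_red0 = 100)
  m <- assemble_model(genotype_preset("abiotic"), p)
  tr <- simulate_etc(m, seq(0, 5, by = 0.25))
  expect_equal(tr$PCA_red, 100 * exp(-1e-6 * 1e6 * tr$time_h), tolerance = 1e-3)
})

test_that("conservation laws hold across random parameter draws", {
  withr::with_seed(101, {
    for (i in 1:20) {
      m <- random_model()
      spikes <- if (runif(1) < 0.3) data.frame(time = 20, amount = 500) else NULL
      tr <- simulate_etc(m, seq(0, 48, by = 1), spikes = spikes)
      errs <- conservation_errors(tr)
      expect_true(all(errs < 1e-6), info = paste(names(errs), signif(errs, 3), collapse = " "))
    }
  })
})

test_that("phenazine is non-increasing when pools start oxidized and no reverse term", {
  withr::with_seed(7, {
    for (i in 1:10) {
      m <- random_model()
      m$params$q_red_frac0 <- 0
      m$params$k_reduce <- 0
      tr <- simulate_etc(m, seq(0, 48, by = 1))
      expect_true(all(diff(tr$PCA_red) <= 1e-8))
    }
  })
})

test_that("oxidation halts on TEA exhaustion and resumes on a spike", {
  p <- model_params(TEA0 = 50)
  m <- assemble_model(genotype_preset("wildtype"), p)
  spikes <- data.frame(time = 30, amount = 500)
  tr <- simulate_etc(m, seq(0, 48, by = 0.25), spikes = spikes)
  pre <- tr$ox_flux[tr$time_h == 29.75]
  post <- tr$ox_flux[tr$time_h == 30.5]
  expect_lt(pre, 0.2)
  expect_gt(post, 10 * pre)
  # without a spike the flux stays off
  tr0 <- simulate_etc(m, seq(0, 48, by = 0.25))
  expect_lt(max(tr0$ox_flux[tr0$time_h > 30]), 0.2)
})

test_that("transport-delay lag reduces to the no-lag model at zero and delays otherwise", {
  g <- genotype_preset("wildtype")
  tr0 <- simulate_etc(assemble_model(g, model_params(lag = 0)), seq(0, 24, 0.5))
  tr_def <- simulate_etc(assemble_model(g, model_params()), seq(0, 24, 0.5))
  expect_equal(tr0$PCA_red, tr_def$PCA_red, tolerance = 1e-12)
  tr_lag <- simulate_etc(assemble_model(g, model_params(lag = 6)), seq(0, 24, 0.5))
  expect_gt(tr_lag$PCA_red[tr_lag$time_h == 6], tr0$PCA_red[tr0$time_h == 6])
})

test_that("knockout wiring: missing reductases and quinones contribute zero flux", {
  # all nitrate reductases gone, k3 = 0: total oxidation flux identically zero
  g3 <- knockout(genotype_preset("wildtype"), "napA", "narG", "narZ")
  m <- assemble_model(g3, null_params(k2 = c(UQ = 0.15, MQ = 0.15, DMQ = 0.15)))
  tr <- simulate_etc(m, seq(0, 48, 1))
  expect_equal(max(abs(tr$ox_flux)), 0)
  expect_equal(tr$PCA_red, rep(100, nrow(tr)), tolerance = 1e-8)
  # quinone-null with narG intact: only category 1 and 3 remain
  gq <- knockout(genotype_preset("wildtype"), "menA", "ubiC")
  mq <- assemble_model(gq, model_params())
  expect_identical(mq$quinones, character(0))
  trq <- simulate_etc(mq, seq(0, 48, 1))
  expect_gt(max(trq$ox_flux), 0)
  # wild type on fumarate: UQ pool has no consumer (Frd does not engage UQ)
  mf <- assemble_model(genotype_preset("wildtype"), model_params(), acceptor = "fumarate")
  trf <- simulate_etc(mf, seq(0, 48, 1))
  expect_equal(trf$Q_red_UQ, rep(trf$Q_red_UQ[1], nrow(trf)), tolerance = 1e-9)
  expect_gt(diff(range(trf$Q_red_MQ)), 0)
  expect_error(assemble_model(genotype_preset("wildtype"), acceptor = "oxygen"),
               "unknown terminal")
})

test_that("optional net-reduction term produces negative observed rates", {
  # cells further reduce a partially oxidized phenazine stock: the
  # fluorescence rises, the observed "oxidation" rate is negative, and the
  # half-oxidation threshold is never reached
  g3 <- knockout(genotype_preset("wildtype"), "napA", "narG", "narZ")
  p <- model_params(k3 = 0, k_reduce = 0.05, PCA_red0 = 80, PCA_ox0 = 30)
  tr <- simulate_etc(assemble_model(g3, p), seq(0, 24, 0.25))
  expect_true(all(diff(tr$PCA_red) >= 0))
  met <- extract_metrics(oxidation_curve(tr$time_h, tr$PCA_red))
  expect_lt(met$max_rate, 0)
  expect_false(met$detected)
  errs <- conservation_errors(tr)
  expect_lt(errs[["phenazine"]], 1e-6)
})

test_that("knockout panel reproduces the headline genotype phenotypes", {
  wt <- genotype_preset("wildtype")
  panel <- knockout_panel(list(
    wildtype = wt,
    triple_KO = knockout(wt, "napA", "narG", "narZ"),
    quinone_null = knockout(wt, "menA", "ubiC"),
    abiotic = genotype_preset("abiotic")))
  r <- setNames(panel$max_rate, panel$strain)
  expect_gt(r[["wildtype"]], r[["abiotic"]])
  expect_equal(r[["triple_KO"]], r[["abiotic"]], tolerance = 1e-9)
  expect_gt(r[["quinone_null"]], r[["abiotic"]])
  expect_lt(r[["quinone_null"]], r[["wildtype"]])
})
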