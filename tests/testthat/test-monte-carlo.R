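test_that("distribution specs validate family parameters", {
  expect_s3_class(dist_spec("BW", "normal", mean = 70, sd = 14), "distribution_spec")
  expect_error(dist_spec("BW", "normal", mean = 70), "sd")
  expect_error(dist_spec("BW", "normal", mean = 70, sd = -1), ">= 0")
  expect_error(dist_spec("u", "uniform", min = 2, max = 1), "min < max")
  expect_error(dist_spec("t", "triangular", min = 0, mode = 5, max = 3), "triangular")
  expect_error(dist_spec("x", "point", value = 1, truncation = c(0, 2)), "point mass")
  expect_error(dist_spec("x", "uniform", min = 0, max = 1, truncation = c(2, 1)),
               "lower < upper")
})

test_that("sampling honors family, truncation and seed determinism", {
  expect_equal(sample_dist(dist_spec("k", "point", value = 7), 5, seed = 1), rep(7, 5))

  # lognormal median recovery at 1e5 draws: within 2% of exp(meanlog)
  sp <- dist_spec("c", "lognormal", meanlog = 2, sdlog = 0.7)
  x <- sample_dist(sp, 1e5, seed = 2)
  expect_lt(abs(stats::median(x) - exp(2)) / exp(2), 0.02)

  # truncation bounds are exact
  tr <- dist_spec("u", "uniform", min = 0, max = 1, truncation = c(0.4, 0.6))
  y <- sample_dist(tr, 1000, seed = 3)
  expect_true(all(y >= 0.4 & y <= 0.6))

  expect_identical(sample_dist(sp, 100, seed = 5), sample_dist(sp, 100, seed = 5))
  expect_false(identical(sample_dist(sp, 100, seed = 5), sample_dist(sp, 100, seed = 6)))

  # triangular quantile/cdf closed forms are consistent and bounded
  tri <- dist_spec("t", "triangular", min = 50, mode = 100, max = 200)
  z <- sample_dist(tri, 5000, seed = 4)
  expect_true(all(z >= 50 & z <= 200))
  expect_lt(abs(mean(z) - (50 + 100 + 200) / 3) / ((50 + 100 + 200) / 3), 0.02)
})

test_that("default distribution builder matches sample moments and flags constants", {
  ct <- generate_site_samples(moro_spec(), seed = 77)
  p <- load_exposure_parameters()
  tox <- load_toxicity_profiles()
  specs <- build_default_distributions(ct, p, tox)
  expect_setequal(names(specs),
                  c("IngRs", "BW", paste0("Cs_", c("Pb", "As", "Cd", "Cr")),
                    paste0("SF_", c("Pb", "As", "Cd", "Cr"))))
  expect_equal(specs$BW$pars$mean, 70)
  expect_equal(specs$IngRs$pars, list(min = 50, mode = 100, max = 200))

  # lognormal moment matching: E[X] = exp(mu + s2/2) equals the sample mean
  as_spec <- specs$Cs_As
  mu <- as_spec$pars$meanlog; s <- as_spec$pars$sdlog
  expect_equal(exp(mu + s^2 / 2), mean(ct[, "As"]), tolerance = 1e-12)
  expect_equal(as_spec$truncation, range(ct[, "As"]))

  const <- concentration_table(cbind(As = rep(5, 4)), "c")
  expect_warning(sc <- build_default_distributions(const, p, tox), "point mass")
  expect_identical(sc$Cs_As$family, "point")
})

test_that("point-mass simulation reproduces the deterministic pipeline exactly", {
  ct <- toy_table()
  p <- load_exposure_parameters()
  tox <- load_toxicity_profiles()
  det <- suppressWarnings(assess_site(ct, p, tox, pathways = "ingestion"))
  specs <- list()
  for (m in c("As", "Pb")) {
    specs[[paste0("Cs_", m)]] <- dist_spec(paste0("Cs_", m), "point", value = mean(ct[, m]))
    specs[[paste0("SF_", m)]] <- dist_spec(paste0("SF_", m), "point", value = tox[[m]]$SF_ing)
  }
  sim <- run_simulation(ct, p, tox, specs = specs, n_iterations = 200, seed = 9)
  expect_equal(unique(sim$draws[, "ILCR_total"]), det$ilcr_total, tolerance = 1e-15)
  expect_true(all(sim$draws[, "ILCR_As"] == sim$draws[1, "ILCR_As"]))
  smry <- sim$summary
  tot <- smry[smry$output == "ILCR_total", ]
  expect_equal(tot$p5, det$ilcr_total, tolerance = 1e-15)
  expect_equal(tot$p95, det$ilcr_total, tolerance = 1e-15)
})

test_that("scaled-lognormal model recovers its closed-form median", {
  # ILCR = Cs * k with Cs ~ lognormal: median is k * exp(meanlog)
  ct <- concentration_table(cbind(As = c(10, 20, 30, 40)), "s")
  p <- load_exposure_parameters()
  tox <- load_toxicity_profiles()
  k <- p$IngRs * p$EF * p$ED * p$CF / (p$BW * p$AT_ca) * tox$As$SF_ing
  mu <- 3
  specs <- list(
    IngRs = dist_spec("IngRs", "point", value = p$IngRs),
    BW = dist_spec("BW", "point", value = p$BW),
    Cs_As = dist_spec("Cs_As", "lognormal", meanlog = mu, sdlog = 0.5),
    SF_As = dist_spec("SF_As", "point", value = tox$As$SF_ing))
  sim <- run_simulation(ct, p, tox, specs = specs, n_iterations = 20000, seed = 10)
  p50 <- sim$summary[sim$summary$output == "ILCR_total", "p50"]
  expect_lt(abs(p50 - k * exp(mu)) / (k * exp(mu)), 0.03)
})

test_that("simulations are seed-deterministic, quantile-monotone and convergent", {
  ct <- generate_site_samples(ifelodun_spec(), seed = 55)
  s1 <- run_simulation(ct, n_iterations = 10000, seed = 42)
  s2 <- run_simulation(ct, n_iterations = 10000, seed = 42)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$summary, s2$summary)

  smry <- s1$summary
  expect_true(all(smry$p5 <= smry$p50 & smry$p50 <= smry$p95))
  expect_true(all(s1$draws >= 0))
  expect_true(all(smry$prob_gt_1e6 >= 0 & smry$prob_gt_1e6 <= 1, na.rm = TRUE))

  # p50 at 10k within 5% of p50 at 100k
  s3 <- run_simulation(ct, n_iterations = 1e5, seed = 43)
  p50a <- smry[smry$output == "ILCR_total", "p50"]
  p50b <- s3$summary[s3$summary$output == "ILCR_total", "p50"]
  expect_lt(abs(p50a - p50b) / p50b, 0.05)

  # missing model symbol errors before sampling
  expect_error(run_simulation(ct, specs = list(IngRs = dist_spec("IngRs", "point", value = 100)),
                              n_iterations = 10, seed = 1),
               "no distribution spec for model symbol")
})

test_that("mean simulated risk dominates risk at mean inputs (convexity in 1/BW)", {
  ct <- concentration_table(cbind(As = rep(20, 4)), "s")
  p <- load_exposure_parameters()
  tox <- load_toxicity_profiles()
  specs <- list(
    IngRs = dist_spec("IngRs", "point", value = p$IngRs),
    BW = dist_spec("BW", "uniform", min = 40, max = 100),
    Cs_As = dist_spec("Cs_As", "point", value = 20),
    SF_As = dist_spec("SF_As", "point", value = tox$As$SF_ing))
  sim <- suppressWarnings(run_simulation(ct, p, tox, specs = specs,
                                         n_iterations = 20000, seed = 11))
  det <- ilcr(cdi_ingestion(20, load_exposure_parameters(list(BW = 70)), "ca"), tox$As$SF_ing)
  mean_sim <- mean(sim$draws[, "ILCR_total"])
  expect_gt(mean_sim, det)
})

test_that("percentile summaries interpolate order statistics and label bands", {
  res <- list(draws = cbind(ILCR_total = (1:100) * 1e-6))
  smry <- summarize_simulation(res)
  expect_equal(smry$p50, 5.05e-5, tolerance = 1e-12)
  expect_identical(smry$band_p50, "acceptable")

  low <- summarize_simulation(list(draws = cbind(ILCR_total = rep(5e-7, 50))))
  expect_identical(low$band_p5, "negligible")
  expect_identical(low$band_p50, "negligible")
  expect_identical(low$band_p95, "negligible")

  three <- summarize_simulation(res, percentiles = c(95, 5, 50))
  expect_true(three$p5 <= three$p50 && three$p50 <= three$p95)
  expect_error(summarize_simulation(list(draws = matrix(0, 0, 1))), "no draws")
  expect_error(summarize_simulation(res, percentiles = c(0, 50)), "between")
})
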