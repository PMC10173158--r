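p0 <- load_exposure_parameters()
tox0 <- load_toxicity_profiles()

test_that("chronic daily intakes match hand arithmetic under the defaults", {
  # Cs x IngRs x EF x ED x CF / (BW x AT_nc): 23.17*100*350*30*1e-6/(70*10950)
  expect_equal(cdi_ingestion(23.17, p0), 3.1739726e-05, tolerance = 1e-6)
  # Cs x InhRs x EF x ED / (PEF x BW x AT_nc)
  expect_equal(cdi_inhalation(23.17, p0), 4.6676065e-09, tolerance = 1e-6)
  # Cs x SA x AF x ABS_As x EF x ED x CF / (BW x AT_nc)
  expect_equal(cdi_dermal(23.17, p0, "As"), 3.7992455e-06, tolerance = 1e-6)

  expect_equal(cdi_ingestion(0, p0), 0)
  expect_equal(cdi_inhalation(0, p0), 0)
  expect_equal(cdi_dermal(0, p0, "Pb"), 0)
})

test_that("CDIs are linear in Cs/EF/ED and inversely linear in BW/AT", {
  withr::with_seed(6, cs <- runif(5, 1, 500))
  expect_equal(cdi_ingestion(2 * cs, p0), 2 * cdi_ingestion(cs, p0))
  # EF doubled -> intake doubled; BW doubled -> halved
  expect_equal(cdi_ingestion(cs, load_exposure_parameters(list(EF = 2 * 175))) /
                 cdi_ingestion(cs, load_exposure_parameters(list(EF = 175))),
               rep(2, 5), tolerance = 1e-12)
  expect_equal(cdi_ingestion(cs, load_exposure_parameters(list(BW = 2 * p0$BW))) /
                 cdi_ingestion(cs, p0), rep(0.5, 5), tolerance = 1e-12)
  # ED halved at fixed AT -> intake halved
  p_ed <- load_exposure_parameters(list(ED = p0$ED / 2, AT_nc = p0$AT_nc))
  expect_equal(cdi_ingestion(cs, p_ed) / cdi_ingestion(cs, p0), rep(0.5, 5),
               tolerance = 1e-12)
  # AT doubled -> intake halved
  p_at <- load_exposure_parameters(list(AT_nc = 2 * p0$AT_nc))
  expect_equal(cdi_ingestion(cs, p_at) / cdi_ingestion(cs, p0), rep(0.5, 5),
               tolerance = 1e-12)
  # PEF -> larger drives inhalation toward 0 monotonically
  pefs <- c(1e9, 1e10, 1e11)
  vals <- vapply(pefs, function(pef) {
    cdi_inhalation(10, load_exposure_parameters(list(PEF = pef)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # dermal scales linearly in SA
  p_sa <- load_exposure_parameters(list(SA = 2 * p0$SA))
  expect_equal(cdi_dermal(cs, p_sa, "As"), 2 * cdi_dermal(cs, p0, "As"))
})

test_that("carcinogenic averaging never exceeds the non-carcinogenic intake", {
  withr::with_seed(13, cs <- runif(20, 0, 1000))
  expect_true(all(cdi_ingestion(cs, p0, "ca") <= cdi_ingestion(cs, p0, "nc")))
  expect_true(all(cdi_dermal(cs, p0, "Cd", "ca") <= cdi_dermal(cs, p0, "Cd", "nc")))
})

test_that("HQ, HI and ILCR implement their defining ratios and sums", {
  expect_equal(hazard_quotient(3e-4, 3e-4), 1)
  expect_equal(hazard_quotient(0, 3e-4), 0)
  expect_equal(hazard_quotient(3.17e-5, 3e-4), 1.056667e-1, tolerance = 1e-6)
  expect_error(hazard_quotient(1, 0), "positive")

  expect_equal(hazard_index(c(0, 0, 0)), 0)
  expect_equal(signif(hazard_index(c(2.93e-1, 9.08e-4, 4.39e-2)), 3), 3.38e-1)
  expect_equal(signif(hazard_index(c(8.32e-2, 6.73e-4, 3.97e-2)), 3), 1.24e-1)

  expect_equal(ilcr(1.62e-3, 1.5), 2.43e-3)
  expect_equal(ilcr(1, 0), 0)
  # monotone nondecreasing in both arguments
  expect_true(ilcr(2e-3, 1.5) >= ilcr(1.62e-3, 1.5))
  expect_true(ilcr(1.62e-3, 2) >= ilcr(1.62e-3, 1.5))
})

test_that("risk classification applies the HI and ILCR thresholds", {
  expect_identical(classify_risk(0.338, 2.63e-3), list(noncancer = "acceptable", cancer = "high"))
  expect_identical(classify_risk(0, 0), list(noncancer = "acceptable", cancer = "negligible"))
  expect_identical(classify_risk(1.5, 5e-5), list(noncancer = "elevated", cancer = "acceptable"))
  expect_identical(classify_risk(1, 1e-6)$noncancer, "elevated")
  expect_identical(classify_risk(0.5, 1e-4)$cancer, "acceptable")  # boundary inclusive
  expect_error(classify_risk(-1, 0), "finite")
})

test_that("assess_site composes the pieces consistently", {
  ct <- toy_table()
  res <- suppressWarnings(assess_site(ct, p0, tox0))

  # HI equals the pathway THQ sum exactly
  expect_identical(res$hi, sum(res$thq))
  # single metal, single pathway degenerates to hazard_quotient o cdi_ingestion
  one <- concentration_table(cbind(As = c(18, 22, 26, 30)), "one")
  r1 <- assess_site(one, p0, tox0, pathways = "ingestion")
  expect_identical(r1$hi, hazard_quotient(cdi_ingestion(mean(one[, "As"]), p0),
                                          tox0$As$RfD_ing))
  expect_identical(r1$ilcr_total, ilcr(cdi_ingestion(mean(one[, "As"]), p0, "ca"),
                                       tox0$As$SF_ing))

  # removing the dermal pathway removes exactly the dermal THQ
  r_all <- suppressWarnings(assess_site(ct, p0, tox0))
  r_no_derm <- suppressWarnings(assess_site(ct, p0, tox0, pathways = c("ingestion", "inhalation")))
  expect_equal(r_all$hi - r_no_derm$hi, r_all$thq[["dermal"]], tolerance = 1e-15)

  # metals without RfD warn and are skipped, not zeroed
  w <- capture_warnings(assess_site(ct, p0, tox0))
  expect_true(any(grepl("Mg", w)))
  # all metals missing RfD -> error
  mg_only <- concentration_table(cbind(Mg = c(100, 120)), "mg")
  expect_error(suppressWarnings(assess_site(mg_only, p0, tox0)), "no metal has a reference dose")

  # all-zero concentrations give HI = 0, acceptable/negligible
  zero <- concentration_table(cbind(As = c(0, 0), Pb = c(0, 0)), "z")
  rz <- assess_site(zero, p0, tox0)
  expect_equal(rz$hi, 0)
  expect_identical(rz$classification$noncancer, "acceptable")
  expect_identical(rz$classification$cancer, "negligible")
})
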