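test_that("lipid content reproduces the batch endpoint percentages", {
  expect_equal(lipid_content(7.02, 12.56), 55.89, tolerance = 1e-2)
  expect_equal(lipid_content(4.48, 10.63), 42.14, tolerance = 1e-2)
  expect_equal(lipid_content(0, 5), 0)
  expect_error(lipid_content(1, 0), "DCW")
  expect_error(lipid_content(6, 5), "exceeds")
})

test_that("productivities and consumption rates are simple rate quotients", {
  expect_equal(productivity(7.02, 120), 0.0585, tolerance = 1e-4)
  expect_equal(productivity(4.48, 120), 0.0373, tolerance = 1e-3)
  expect_equal(productivity(0, 7), 0)
  expect_error(productivity(1, 0), "> 0")
  expect_equal(consumption_rate(30, 0, 120), 0.25)
  expect_equal(consumption_rate(5, 5, 10), 0)
  expect_equal(consumption_rate(37.38, 31.91, 120), 0.0456,
               tolerance = 1e-3)
  expect_warning(consumption_rate(1, 2, 10), "production")
})

test_that("rates are additive over adjacent windows", {
  set.seed(3)
  t <- c(0, sort(runif(5, 1, 119)), 120)
  conc <- cumsum(c(0, runif(6, 0, 2)))
  sub <- vapply(1:6, function(i) {
    productivity(conc[i + 1] - conc[i], t[i + 1] - t[i])
  }, 1.0)
  weighted <- sum(sub * diff(t)) / 120
  expect_equal(weighted, productivity(conc[7] - conc[1], 120),
               tolerance = 1e-12)
})

test_that("utilization percentages match the trace-element accounting", {
  expect_equal(utilization_percent(107, 6.3), 94.11, tolerance = 1e-2)
  expect_equal(utilization_percent(0.37, 0.24), 35.14, tolerance = 1e-2)
  expect_equal(utilization_percent(2, 2), 0)
  expect_error(utilization_percent(0, 1), "> 0")
  # bounded in [0, 100] whenever after <= before
  set.seed(5)
  b <- runif(50, 0.1, 100)
  a <- b * runif(50)
  u <- utilization_percent(b, a)
  expect_true(all(u >= 0 & u <= 100))
})

test_that("sugar totals and detox losses reproduce the stream accounting", {
  expect_equal(total_sugars(c(28.05, 18.13, 0.29)), 46.47, tolerance = 1e-9)
  expect_equal(total_sugars(c(0.45, 29.01, 2.45)), 31.91, tolerance = 1e-9)
  expect_equal(total_sugars(numeric(0)), 0)
  expect_equal(detox_loss_percent(37.38, 31.91), 14.63, tolerance = 1e-2)
  expect_equal(detox_loss_percent(5.61, 0.11), 98.04, tolerance = 1e-2)
  expect_equal(detox_loss_percent(3, 3), 0)
})

test_that("fold changes match the reported morphology ratios", {
  expect_equal(fold_change(7.43, 6.26), 1.187, tolerance = 1e-3)
  expect_equal(fold_change(107, 6.3), 16.98, tolerance = 1e-2)
  expect_equal(fold_change(4, 4), 1)
  expect_error(fold_change(1, 0), "> 0")
})

test_that("single-point HPLC quantification is linear in peak area", {
  expect_equal(hplc_quantify(100, 100), 1.0)
  expect_equal(hplc_quantify(200, 100), 2.0)
  expect_equal(hplc_quantify(0, 50), 0)
  expect_equal(hplc_quantify(150, 100, standard_conc = 2), 3.0)
  expect_error(hplc_quantify(1, 0), "calibration")
})

test_that("the mass-balance ledger chains shells to biodiesel", {
  mb <- mass_balance(20, 12.8, 6.8, 0.9177)
  expect_equal(mb$amount_g_l[mb$stage == "biodiesel"], 6.24,
               tolerance = 1e-2)
  expect_equal(mb$yield_pct_of_previous[mb$stage == "lipid"], 53.1,
               tolerance = 1e-1)
  # non-increasing along the chain past the shells stage
  expect_true(all(diff(mb$amount_g_l[-1]) <= 0))
  zero <- mass_balance(20, 12.8, 0, 0.9)
  expect_equal(zero$amount_g_l[zero$stage == "biodiesel"], 0)
  expect_error(mass_balance(20, 12.8, 6.8, 1.2), "\\[0, 1\\]")
})

test_that("time-course invariants are enforced", {
  expect_error(time_course(c(1, 2), c(1, 2), c(0, 0)), "must be 0")
  expect_error(time_course(c(0, 0), c(1, 2), c(0, 0)), "increasing")
  expect_error(time_course(c(0, 10), c(1, 2), c(0.5, 3)), "exceeds DCW")
  expect_error(time_course(c(0, 10), c(1, 2), c(0, -1)), ">= 0")
})

test_that("endpoint kinetics recover the batch summary from a time course", {
  tc <- read_timecourse_csv(extdata("timecourse_as_psh_synthetic.csv"))
  k <- kinetics(tc)
  expect_equal(k$lipid_content, 55.89, tolerance = 1e-2)
  expect_equal(k$lipid_productivity, 7.02 / 120, tolerance = 1e-9)
  expect_equal(k$biomass_productivity, (12.56 - 0.1) / 120,
               tolerance = 1e-9)
  expect_equal(unname(k$consumption_rate["glucose"]), 28.05 / 120,
               tolerance = 1e-9)
  # windowed variant
  kw <- kinetics(tc, window = c(0, 60))
  expect_equal(unname(kw$window), c(0, 60))
  km <- kinetics(tc, method = "max-slope")
  expect_gte(km$lipid_productivity, k$lipid_productivity)
})

test_that("missing t=0 sugar samples fall back to the medium recipe", {
  tc <- time_course(c(0, 60, 120), dcw = c(0.2, 6, 12),
                    lipid_titre = c(0, 2, 6),
                    sugars = data.frame(glucose = c(NA, 12, 0)))
  k <- kinetics(tc, initial_sugars = c(glucose = 30))
  expect_equal(unname(k$consumption_rate["glucose"]), 0.25)
  k_na <- kinetics(tc)
  expect_true(is.na(k_na$consumption_rate["glucose"]))
})

test_that("hydrolysate composition carries units and missing entries", {
  hc <- read_hydrolysate_csv(extdata("hydrolysate_as_psh.csv"))
  expect_s3_class(hc, "hydrolysate_composition")
  ca <- hc[hc$analyte == "calcium", ]
  expect_equal(ca$unit, "mg/L")
  expect_equal(ca$before_g_l, 0.107)  # mg/L converted internally
  expect_true(is.na(hc$after[hc$analyte == "glucose"]))
  expect_equal(total_sugars(hc), 46.47, tolerance = 1e-9)

  u <- utilization_table(hc)
  expect_equal(u$utilization_pct[u$analyte == "calcium"], 94.11,
               tolerance = 1e-2)
  expect_equal(u$utilization_pct[u$analyte == "manganese"], 35.14,
               tolerance = 1e-2)
  expect_true(is.na(u$utilization_pct[u$analyte == "glucose"]))
  # detection-limit substitution brings not-detected analytes into the math
  u2 <- utilization_table(hc, detection_limit = 0)
  expect_equal(u2$utilization_pct[u2$analyte == "glucose"], 100)
})

test_that("pretreatment records enforce the detox direction", {
  pr <- pretreatment_record("acid-liquid", 20, 37.38, 31.91,
                            inhibitors = c("acetic acid" = 5.61))
  expect_equal(detox_loss_percent(pr$sugars_before, pr$sugars_after),
               14.63, tolerance = 1e-2)
  expect_error(pretreatment_record("acid-liquid", 20, 30, 35),
               "cannot increase")
})
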