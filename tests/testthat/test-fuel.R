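oleate <- fame_profile(c("C18:1" = 100))
palmitate <- fame_profile(c("C16:0" = 100))

test_that("pure-component SV/IV/CN/HHV match hand-derived values", {
  expect_equal(saponification_value(oleate), 560 * 100 / 296.495,
               tolerance = 1e-9)
  expect_equal(saponification_value(oleate), 188.9, tolerance = 1e-3)
  expect_equal(saponification_value(palmitate), 207.0, tolerance = 1e-3)
  expect_equal(iodine_value(palmitate), 0)
  expect_equal(iodine_value(oleate), 85.7, tolerance = 1e-3)
  expect_equal(cetane_number(oleate, "per-species"), 55.9, tolerance = 1e-2)
  expect_equal(higher_heating_value(oleate), 40.4, tolerance = 1e-2)
  expect_equal(higher_heating_value(palmitate), 40.9, tolerance = 1e-2)
})

test_that("du/lcsf regressions return their intercepts at zero predictors", {
  s0 <- class_summary(palmitate)  # du = 0
  expect_equal(cetane_number(palmitate, "du-regression"), 62.876)
  expect_equal(kinematic_viscosity(s0), 5.2065)
  expect_equal(fuel_density(s0), 0.8726)
  expect_equal(cfpp(class_summary(oleate)), -16.477)  # lcsf = 0
  expect_equal(cfpp(s0), 3.1417 * 10 - 16.477, tolerance = 1e-9)
  expect_equal(kinematic_viscosity(class_summary(oleate)), 4.5749,
               tolerance = 1e-9)
})

test_that("SV and IV are linear in the weight percents", {
  p <- fame_profile(as_psh_fractions)
  half <- fame_profile(as_psh_fractions / 2)
  expect_equal(saponification_value(half), saponification_value(p) / 2,
               tolerance = 1e-12)
  expect_equal(iodine_value(half), iodine_value(p) / 2, tolerance = 1e-12)
})

test_that("vectorized SV/IV equal the per-component loop oracle", {
  set.seed(7)
  for (i in 1:200) {
    p <- random_profile(sample(3:10, 1))
    o <- oracle_sv_iv(p$fractions)
    expect_equal(saponification_value(p), unname(o["sv"]), tolerance = 1e-9)
    expect_equal(iodine_value(p), unname(o["iv"]), tolerance = 1e-9)
  }
})

test_that("properties are invariant under species-order permutation", {
  set.seed(11)
  p <- random_profile(8)
  q <- p
  idx <- sample(8)
  q$fractions <- q$fractions[idx]
  for (f in list(saponification_value, iodine_value, higher_heating_value)) {
    expect_equal(f(q), f(p), tolerance = 1e-12)
  }
  expect_equal(cetane_number(q, "per-species"),
               cetane_number(p, "per-species"), tolerance = 1e-12)
})

test_that("CN and KV decrease, density increases, strictly in DU", {
  du <- seq(0, 3, by = 0.25)
  mk <- function(d) {
    # mufa fraction d of the simplex gives du = d when pufa = 0
    structure(list(sfa = 100 * (1 - d / 3), mufa = 100 * d / 3 * 3 / 3,
                   pufa = 0, du = d, lcsf = 0, total = 100),
              class = "class_summary")
  }
  kv <- vapply(du, function(d) kinematic_viscosity(mk(d)), 1.0)
  rho <- vapply(du, function(d) fuel_density(mk(d)), 1.0)
  expect_true(all(diff(kv) < 0))
  expect_true(all(diff(rho) > 0))
  expect_true(all(rho >= 0.8726 & rho <= 0.88911))
  co <- fuel_correlations("du-regression")$cn_du
  cn <- co["intercept"] + co["du"] * du
  expect_true(all(diff(cn) < 0))
})

test_that("iodine value is zero iff the profile is fully saturated", {
  set.seed(13)
  for (i in 1:20) {
    p <- random_profile(6)
    sp <- parse_species(names(p$fractions))
    has_unsat <- any(sp$double_bonds > 0 & p$fractions > 0)
    expect_identical(iodine_value(p) > 1e-12, has_unsat)
  }
})

test_that("replacing unsaturated mass by C16:0 never decreases CFPP", {
  base <- c("C18:1" = 40, "C18:2" = 20, "C16:0" = 30, "C18:0" = 10)
  for (shift in c(0, 10, 20, 40)) {
    f <- base
    take <- min(shift, f["C18:1"])
    f["C18:1"] <- f["C18:1"] - take
    f["C16:0"] <- f["C16:0"] + take
    if (shift == 0) {
      cf_prev <- cfpp(class_summary(fame_profile(f)))
    } else {
      cf <- cfpp(class_summary(fame_profile(f)))
      expect_gte(cf, cf_prev)
      cf_prev <- cf
    }
  }
})

test_that("degenerate profiles surface as errors", {
  expect_error(saponification_value(fame_profile(c("C18:1" = 0))),
               "degenerate")
  expect_error(cetane_number(fame_profile(c("C18:1" = 0))), "degenerate")
})

test_that("standards verdicts follow the printed limit grid", {
  p <- fame_profile(as_psh_fractions, "AS-PSH")
  rep <- fuel_property_report(p, method = "du-regression")
  v_is <- evaluate_standards(rep, "IS15607")
  expect_equal(v_is$verdict[v_is$property == "cn"], "pass")  # CN > 51
  expect_equal(attr(v_is, "overall"), "pass")
  v_en <- evaluate_standards(rep, "EN14214")
  expect_equal(v_en$verdict[v_en$property == "iv"], "pass")  # IV < 120
  expect_equal(v_en$verdict[v_en$property == "hhv"], "not-specified")
  # a CN below the printed EN minimum of 47 fails
  low <- rep
  low$cn <- 46
  v_low <- evaluate_standards(low, "EN14214")
  expect_equal(v_low$verdict[v_low$property == "cn"], "fail")
  expect_equal(attr(v_low, "overall"), "fail")
  expect_error(evaluate_standards(rep, "EN99999"))
})

test_that("the literature limit set swaps the EN/ASTM cetane minima", {
  lit <- fuel_standards("literature")
  asp <- fuel_standards("as-printed")
  cn_min <- function(df, std) df$min[df$standard == std & df$property == "cn"]
  expect_equal(cn_min(asp, "EN14214"), 47)
  expect_equal(cn_min(lit, "EN14214"), 51)
  expect_equal(cn_min(asp, "ASTMD6751"), 51)
  expect_equal(cn_min(lit, "ASTMD6751"), 47)
})

test_that("biodiesel mass and efficiency are exact inverses", {
  expect_equal(estimate_biodiesel_mass(6.8, 0.9177), 6.24, tolerance = 1e-2)
  expect_equal(estimate_biodiesel_mass(3.1, 1), 3.1)
  expect_equal(transesterification_efficiency(6.24, 6.8), 0.91765,
               tolerance = 1e-4)
  for (m in c(0.5, 2, 6.8)) {
    for (e in c(0, 0.5, 0.9177, 1)) {
      expect_equal(transesterification_efficiency(
        estimate_biodiesel_mass(m, e), m), e, tolerance = 1e-12)
    }
  }
  expect_error(estimate_biodiesel_mass(1, 1.2), "efficiency")
  expect_error(estimate_biodiesel_mass(-1, 0.5))
})
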