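test_that("identical seeds give bit-identical generator output", {
  p <- growth_sim_params(noise_sd = 0.3, seed = 99)
  t1 <- simulate_timecourse(p)
  t2 <- simulate_timecourse(p)
  expect_identical(t1, t2)
  s1 <- simulate_screening_table(57, seed = 7)
  s2 <- simulate_screening_table(57, seed = 7)
  expect_identical(s1, s2)
  h1 <- simulate_hydrolysate(seed = 5)
  h2 <- simulate_hydrolysate(seed = 5)
  expect_identical(h1, h2)
  mean_p <- normalize_profile(fame_profile(as_psh_fractions))
  f1 <- simulate_fame_profile(mean_p, 500, seed = 3)
  f2 <- simulate_fame_profile(mean_p, 500, seed = 3)
  expect_identical(f1, f2)
})

test_that("logistic growth approaches carrying capacity and lipid stays below biomass", {
  # beta = 0 so the lipid bound holds on an arbitrarily long horizon
  p <- growth_sim_params(noise_sd = 0, beta = 0)
  tc <- simulate_timecourse(p, times = seq(0, 600, 30))
  expect_equal(tc$dcw[length(tc$dcw)], p$K, tolerance = 1e-6)
  expect_true(all(tc$lipid_titre <= tc$dcw + 1e-12))
  # alpha = beta = 0 gives zero lipid throughout
  p0 <- growth_sim_params(alpha = 0, beta = 0)
  expect_true(all(simulate_timecourse(p0)$lipid_titre == 0))
  # noisy trajectories respect the same invariant by clipping
  pn <- growth_sim_params(noise_sd = 0.5, seed = 17)
  tn <- simulate_timecourse(pn)
  expect_true(all(tn$lipid_titre <= tn$dcw + 1e-12))
  expect_true(all(tn$dcw >= 0))
})

test_that("noiseless endpoint lipid content matches the closed form", {
  # growth-associated production only: L(t) = alpha (X(t) - X0)
  p <- growth_sim_params(X0 = 0.1, K = 12.8, mu = 0.08, alpha = 0.53,
                         beta = 0, noise_sd = 0)
  tc <- simulate_timecourse(p, times = seq(0, 120, 15))
  k <- kinetics(tc)
  x120 <- 12.8 / (1 + ((12.8 - 0.1) / 0.1) * exp(-0.08 * 120))
  expect_equal(k$lipid_content, 100 * 0.53 * (x120 - 0.1) / x120,
               tolerance = 1e-9)
  expect_equal(k$lipid_productivity, 0.53 * (x120 - 0.1) / 120,
               tolerance = 1e-9)
})

test_that("sugars deplete sequentially in preference order", {
  p <- growth_sim_params(noise_sd = 0)
  tc <- simulate_timecourse(p, times = seq(0, 120, 5))
  sg <- tc$sugars
  # xylose untouched until glucose is exhausted
  glu_gone <- min(which(sg$glucose == 0))
  expect_true(all(sg$xylose[seq_len(glu_gone - 1)] == sg$xylose[1]))
  expect_true(all(diff(sg$glucose) <= 0))
  expect_true(all(unlist(sg) >= 0))
  expect_equal(unname(unlist(sg[nrow(sg), ])), c(0, 0, 0))
})

test_that("Dirichlet profile draws live on the 100% simplex", {
  mean_p <- normalize_profile(fame_profile(as_psh_fractions, "AS-PSH"))
  for (s in 1:20) {
    d <- simulate_fame_profile(mean_p, 500, seed = s)
    expect_equal(sum(d$fractions), 100, tolerance = 1e-9)
    expect_true(all(d$fractions >= 0))
  }
  # infinite precision returns the mean exactly
  exact <- simulate_fame_profile(mean_p, Inf)
  expect_equal(exact$fractions, mean_p$fractions, tolerance = 1e-12)
  # non-normalized mean is a parameter error
  expect_error(simulate_fame_profile(fame_profile(as_psh_fractions), 500),
               "normalized")
})

test_that("mean simulated cetane number approaches the mean-profile value", {
  mean_p <- normalize_profile(fame_profile(as_psh_fractions, "AS-PSH"))
  cn_mean <- cetane_number(mean_p, "du-regression")
  set.seed(12)
  cns <- vapply(1:400, function(i) {
    cetane_number(simulate_fame_profile(mean_p, 500), "du-regression")
  }, 1.0)
  mc_se <- stats::sd(cns) / sqrt(length(cns))
  expect_lt(abs(mean(cns) - cn_mean), 4 * mc_se + 0.02)
})

test_that("screening generator hits its correlation target in the limit", {
  t1 <- simulate_screening_table(30, target_r = 1, seed = 2)
  expect_equal(rfu_lipid_correlation(t1)$r, 1.0, tolerance = 1e-9)
  expect_error(simulate_screening_table(2, 0.9), "3 strains")
  expect_error(simulate_screening_table(10, 0), "target_r")
  expect_error(simulate_screening_table(10, 1.5), "target_r")
  t3 <- simulate_screening_table(3, target_r = 0.9, seed = 4)
  expect_equal(nrow(t3), 3)
  # negative targets flip the response sign (offset keeps RFU off the floor)
  tn <- simulate_screening_table(40, target_r = -1, seed = 6, offset = 6000)
  expect_equal(rfu_lipid_correlation(tn)$r, -1.0, tolerance = 1e-9)
})

test_that("hydrolysate generator reproduces the panel exactly at zero noise", {
  h <- simulate_hydrolysate(seed = 1, sd_scale = 0)$composition
  u <- utilization_table(h)
  expect_equal(u$utilization_pct[u$analyte == "calcium"], 94.11,
               tolerance = 1e-2)
  expect_equal(h$before[h$analyte == "glucose"], 28.05)
  expect_equal(total_sugars(h), 46.47, tolerance = 1e-9)
  # any seed yields non-negative concentrations
  for (s in 1:10) {
    hs <- simulate_hydrolysate(seed = s)$composition
    expect_true(all(hs$before_g_l >= 0, na.rm = TRUE))
    expect_true(all(hs$after_g_l >= 0, na.rm = TRUE))
  }
})
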