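# Agreement statistics: hand-computed examples, edge behavior, invariants,
# and brute-force oracle equivalence.

test_that("paired_series computes index measures and respects strata", {
  co <- make_cohort(alm_ref = c(20, 19, 21), height = 1.70)
  s <- paired_series(co, "ALMi", "all")
  expect_equal(s$reference[1], 20 / 1.70^2, tolerance = 1e-12)
  expect_equal(round(s$reference[1], 3), 6.920)
  # height 1 m: index equals mass numerically
  co1 <- make_cohort(alm_ref = c(20, 19), height = 1)
  expect_equal(paired_series(co1, "ALMi", "all")$reference,
               paired_series(co1, "ALM", "all")$reference)
  # stratum sizes
  co2 <- make_two_sex_cohort(10, 20)
  expect_length(paired_series(co2, "ALM", "male")$reference, 10)
  expect_error(paired_series(make_cohort(c(20, 21), sex = "female"),
                             "ALM", "male"), "insufficient")
})

test_that("bias summary matches hand computation", {
  s <- make_series(c(20, 18, 22), c(19, 18.5, 21))
  bs <- bias_summary(s)
  expect_equal(bs$bias_mean, -0.5)
  expect_equal(bs$bias_sd, sd(c(-1, 0.5, -1)))
  expect_equal(round(bs$bias_sd, 3), 0.866)
  ident <- bias_summary(make_series(c(20, 18), c(20, 18)))
  expect_equal(ident$bias_mean, 0)
  expect_equal(ident$bias_sd, 0)
  expect_equal(ident$bias_pct_mean, 0)
})

test_that("accuracy partition uses inclusive 5% boundaries", {
  s <- make_series(rep(20, 4), c(19.0, 18.9, 21.2, 21.0))
  acc <- accuracy_classification(s)
  # 19.0/20 = 0.95 inclusive-accurate; 21.0/20 = 1.05 inclusive-accurate;
  # 18.9 under; 21.2 over
  expect_equal(unname(acc), c(50, 25, 25))
  expect_equal(sum(acc), 100)
  expect_error(accuracy_classification(make_series(c(0, 20), c(1, 20))),
               "positive")
})

test_that("MAE matches hand computation and dominates |bias|", {
  s <- make_series(c(10, 10, 10), c(9, 10.5, 9))
  expect_equal(mean_absolute_error(s), mean(c(1, 0.5, 1)))
  expect_equal(round(mean_absolute_error(s), 4), 0.8333)
  expect_equal(mean_absolute_error(make_series(c(5, 6), c(5, 6))), 0)
  set.seed(4)
  for (i in 1:20) {
    ref <- runif(8, 10, 30)
    cand <- ref + rnorm(8)
    s <- make_series(ref, cand)
    expect_gte(mean_absolute_error(s), abs(bias_summary(s)$bias_mean))
  }
})

test_that("Bland-Altman limits and proportional-bias regression are exact", {
  lo <- loa_limits(-0.60, 1.21)
  expect_equal(unname(round(lo, 1)), c(-3.0, 1.8))
  # closed-form 3-point regression: means (10,20,30), differences (1,2,3)
  ref <- c(10, 20, 30) - c(1, 2, 3) / 2
  cand <- c(10, 20, 30) + c(1, 2, 3) / 2
  ba <- bland_altman(make_series(ref, cand))
  expect_equal(ba$prop_bias$slope, 0.1, tolerance = 1e-12)
  expect_equal(ba$prop_bias$intercept, 0, tolerance = 1e-12)
  expect_equal(ba$prop_bias$r_squared, 1)
  # zero-SD differences: both limits collapse onto the mean bias
  ba0 <- bland_altman(make_series(c(10, 20, 30), c(10, 20, 30) - 2))
  expect_equal(ba0$loa_low, -2)
  expect_equal(ba0$loa_high, -2)
  expect_false(ba0$prop_bias$significant)
  # identical per-subject means: regression degenerate
  expect_error(bland_altman(make_series(c(10, 10, 10), c(10, 10, 10))),
               "degenerate")
  # LoA identity and width
  set.seed(8)
  s <- make_series(runif(20, 15, 25), runif(20, 15, 25))
  ba2 <- bland_altman(s)
  bs <- bias_summary(s)
  expect_equal(ba2$loa_low, bs$bias_mean - 1.96 * bs$bias_sd)
  expect_equal(ba2$loa_high - ba2$loa_low, 3.92 * bs$bias_sd)
})

test_that("percent bias of an index equals percent bias of its mass exactly", {
  co <- generate_cohort(synthetic_params(n_male = 40, n_female = 60, seed = 6))
  for (pair in list(c("ALM", "ALMi"), c("FFM", "FFMi"))) {
    mass <- paired_series(co, pair[1], "all")
    idx <- paired_series(co, pair[2], "all")
    pct_mass <- 100 * (mass$candidate - mass$reference) / mass$reference
    pct_idx <- 100 * (idx$candidate - idx$reference) / idx$reference
    expect_equal(pct_idx, pct_mass, tolerance = 1e-12)
    expect_equal(bias_summary(idx)$bias_pct_mean,
                 bias_summary(mass)$bias_pct_mean, tolerance = 1e-12)
  }
})

test_that("all statistics match the brute-force oracle on small cohorts", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    ref <- runif(n, 12, 30)
    cand <- ref * runif(n, 0.9, 1.1) + rnorm(n, 0, 0.5)
    s <- make_series(ref, cand)
    o <- oracle_agreement(ref, cand)
    a <- agreement_summary(s)
    for (f in c("bias_mean", "bias_sd", "bias_pct_mean", "bias_pct_sd",
                "mae", "pct_accurate", "pct_under", "pct_over",
                "loa_low", "loa_high")) {
      expect_equal(a[[f]], o[[f]], tolerance = 1e-10, label = f)
    }
    expect_equal(a$prop_bias$slope, o$slope, tolerance = 1e-10)
    expect_equal(a$prop_bias$intercept, o$intercept, tolerance = 1e-10)
  }
})

test_that("sex-interaction test separates parallel shift from slope change", {
  set.seed(21)
  n <- 100
  cand_f <- runif(n, 14, 24); cand_m <- runif(n, 20, 32)
  # parallel shift only: no interaction
  co_null <- cohort(data.frame(
    subject_id = sprintf("N%03d", 1:(2 * n)),
    sex = rep(c("female", "male"), each = n),
    age = 70, height_m = 1.7,
    alm_dxa_kg = c(cand_f + rnorm(n, 0, 0.3), cand_m + 5 + rnorm(n, 0, 0.3)),
    alm_bia_kg = c(cand_f, cand_m),
    ffm_dxa_kg = c(cand_f, cand_m) + 40, ffm_bia_kg = c(cand_f, cand_m) + 30))
  res_null <- sex_interaction_test(co_null, "ALM")
  expect_false(res_null$stratify)
  fit <- lm(alm_dxa_kg ~ alm_bia_kg * sex, data = as.data.frame(co_null))
  expect_lt(abs(coef(fit)[["alm_bia_kg:sexmale"]]), 0.05)
  # slope 1 vs slope 0.5: strong interaction
  co_alt <- cohort(data.frame(
    subject_id = sprintf("A%03d", 1:(2 * n)),
    sex = rep(c("female", "male"), each = n),
    age = 70, height_m = 1.7,
    alm_dxa_kg = c(0.5 * cand_f + 10 + rnorm(n, 0, 0.3),
                   cand_m + rnorm(n, 0, 0.3)),
    alm_bia_kg = c(cand_f, cand_m),
    ffm_dxa_kg = c(cand_f, cand_m) + 40, ffm_bia_kg = c(cand_f, cand_m) + 30))
  res_alt <- sex_interaction_test(co_alt, "ALM")
  expect_true(res_alt$stratify)
  expect_lt(res_alt$interaction_p, 0.001)
  # single-sex input refused
  expect_error(sex_interaction_test(make_cohort(runif(10, 15, 25)), "ALM"),
               "insufficient")
})
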