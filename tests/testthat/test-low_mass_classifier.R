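# Quintile cut-offs, low/normal classification, confusion tables, and the
# fixed-cut-off prevalence.

test_that("quintile cut-off interpolates between order statistics", {
  expect_equal(quintile_cutoff(1:10), 2.8)           # h = 1.8 by hand
  expect_equal(quintile_cutoff(sample(1:10)), 2.8)   # order-free
  expect_equal(quintile_cutoff(rep(3.5, 6)), 3.5)    # constant data
  expect_equal(quintile_cutoff(1:10), oracle_quintile(1:10))
  expect_error(quintile_cutoff(1:4), "insufficient")
  # alternative convention is available
  expect_equal(quintile_cutoff(1:10, type = 1), 2)
})

test_that("classification is strictly below the cut-off", {
  expect_true(classify_low(16.0, 16.1))
  expect_false(classify_low(16.1, 16.1))   # tie goes to normal
  expect_false(classify_low(22.8, 22.8))
})

test_that("diagnostic table matches the brute-force double loop", {
  set.seed(17)
  for (rep in 1:40) {
    n_m <- sample(5:10, 1); n_f <- sample(5:10, 1)
    co <- make_two_sex_cohort(n_m, n_f, seed = rep, noise_sd = 1, bias = -0.5)
    expected <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
    for (sx in c("male", "female")) {
      ref <- co$alm_dxa_kg[co$sex == sx]
      cand <- co$alm_bia_kg[co$sex == sx]
      expected <- expected + oracle_confusion(ref, cand, oracle_quintile(ref))
    }
    dt <- diagnostic_table(co, "ALM", "all")
    expect_equal(c(tp = dt$tp, fn = dt$fn, fp = dt$fp, tn = dt$tn), expected)
    expect_equal(dt$sensitivity, 100 * expected[["tp"]] /
                   (expected[["tp"]] + expected[["fn"]]))
    expect_equal(dt$specificity, 100 * expected[["tn"]] /
                   (expected[["tn"]] + expected[["fp"]]))
  }
})

test_that("pooled counts are the sum of the per-sex tables", {
  co <- make_two_sex_cohort(20, 30, seed = 3, noise_sd = 1, bias = -0.5)
  all_t <- diagnostic_table(co, "ALM", "all")
  m <- diagnostic_table(co, "ALM", "male")
  f <- diagnostic_table(co, "ALM", "female")
  expect_equal(all_t$tp, m$tp + f$tp)
  expect_equal(all_t$fn, m$fn + f$fn)
  expect_equal(all_t$fp, m$fp + f$fp)
  expect_equal(all_t$tn, m$tn + f$tn)
  expect_equal(all_t$cutoff, c(male = m$cutoff, female = f$cutoff))
})

test_that("perfect agreement gives perfect sensitivity and specificity", {
  co <- make_two_sex_cohort(15, 15, seed = 5, noise_sd = 0, bias = 0)
  dt <- diagnostic_table(co, "ALM", "all")
  expect_equal(dt$sensitivity, 100)
  expect_equal(dt$specificity, 100)
  expect_equal(dt$fn + dt$fp, 0)
})

test_that("tie-free reference-low fraction is within 1/n of 20% per sex", {
  co <- make_two_sex_cohort(58, 144, seed = 7)
  for (sx in c("male", "female")) {
    ser <- paired_series(co, "ALM", sx)
    cut <- quintile_cutoff(ser$reference)
    frac <- mean(classify_low(ser$reference, cut))
    expect_lte(abs(frac - 0.20), 1 / length(ser$reference))
  }
})

test_that("uniform negative candidate bias moves sens up and spec down", {
  co <- make_two_sex_cohort(40, 60, seed = 13, noise_sd = 1)
  shifted <- co
  shifted$alm_bia_kg <- shifted$alm_bia_kg - 1.5
  base <- diagnostic_table(co, "ALM", "all")
  neg <- diagnostic_table(shifted, "ALM", "all")
  expect_gte(neg$sensitivity, base$sensitivity)
  expect_lte(neg$specificity, base$specificity)
})

test_that("sens/spec invariant under affine maps of both devices", {
  co <- make_two_sex_cohort(30, 40, seed = 23, noise_sd = 1, bias = -0.5)
  tr <- co
  tr$alm_dxa_kg <- 3 * tr$alm_dxa_kg + 7
  tr$alm_bia_kg <- 3 * tr$alm_bia_kg + 7
  tr$ffm_dxa_kg <- 3 * tr$ffm_dxa_kg + 100   # keep ALM < FFM
  tr$ffm_bia_kg <- 3 * tr$ffm_bia_kg + 100
  a <- diagnostic_table(co, "ALM", "all")
  b <- diagnostic_table(tr, "ALM", "all")
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)
  expect_equal(c(a$tp, a$fn, a$fp, a$tn), c(b$tp, b$fn, b$fp, b$tn))
})

test_that("EWGSOP2 prevalence uses strict < on the reference ALM index", {
  # heights of 1 m make the index equal the mass numerically
  alm_m <- c(6.5, 6.5, 6.5, 6.5, 6.9, rep(8, 53))        # 5 of 58 low
  alm_f <- c(rep(5.5, 15), rep(6.0, 5), rep(6.5, 124))   # 15 of 144; 6.0 not low
  co <- cohort(data.frame(
    subject_id = sprintf("E%03d", 1:202),
    sex = c(rep("male", 58), rep("female", 144)),
    age = 70, height_m = 1,
    alm_dxa_kg = c(alm_m, alm_f), alm_bia_kg = c(alm_m, alm_f),
    ffm_dxa_kg = c(alm_m, alm_f) + 30, ffm_bia_kg = c(alm_m, alm_f) + 30))
  prev <- prevalence_ewgsop2(co)
  expect_equal(prev$n_low, c(5, 15))
  expect_equal(prev$prevalence_display, c(9, 10))
  co0 <- make_cohort(rep(30, 6))   # nobody below the cut-off
  expect_equal(prevalence_ewgsop2(co0)$prevalence_display[2], 0)
})
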