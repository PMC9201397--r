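# Builders for small in-code fixtures.

make_cohort <- function(alm_ref, alm_cand = alm_ref, sex = "female",
                        height = 1.7, ffm_ref = alm_ref + 30,
                        ffm_cand = alm_cand + 30, bmi = NULL, fat = NULL,
                        age = 70) {
  n <- length(alm_ref)
  df <- data.frame(
    subject_id = sprintf("T%04d", seq_len(n)),
    sex = rep(sex, length.out = n),
    age = rep(age, length.out = n),
    height_m = rep(height, length.out = n),
    alm_dxa_kg = alm_ref, alm_bia_kg = alm_cand,
    ffm_dxa_kg = ffm_ref, ffm_bia_kg = ffm_cand,
    stringsAsFactors = FALSE
  )
  if (!is.null(bmi)) df$bmi <- bmi
  if (!is.null(fat)) df$fat_pct <- fat
  cohort(df, provenance = "test fixture")
}

# Two-sex cohort with tie-free continuous values.
make_two_sex_cohort <- function(n_male, n_female, seed = 1,
                                noise_sd = 0.5, bias = 0) {
  set.seed(seed)
  mk <- function(n, sex, mu, sd) {
    ref <- mu + sd * stats::qnorm((seq_len(n) - 0.3) / (n + 0.4)) +
      stats::runif(n, -1e-3, 1e-3)
    cand <- ref + bias + stats::rnorm(n, 0, noise_sd)
    data.frame(
      subject_id = sprintf("%s%04d", toupper(substr(sex, 1, 1)), seq_len(n)),
      sex = sex, age = 70,
      height_m = if (sex == "male") 1.75 else 1.63,
      alm_dxa_kg = ref, alm_bia_kg = cand,
      ffm_dxa_kg = ref + 30, ffm_bia_kg = cand + 30,
      stringsAsFactors = FALSE
    )
  }
  cohort(rbind(mk(n_male, "male", 25.6, 3.1), mk(n_female, "female", 18.3, 2.4)),
         provenance = "test two-sex fixture")
}

# Bare paired series for pure-statistics tests.
make_series <- function(ref, cand, measure = "ALM", stratum = "all",
                        unit = "kg") {
  structure(list(measure = measure, stratum = stratum, unit = unit,
                 subject_ids = as.character(seq_along(ref)),
                 reference = ref, candidate = cand),
            class = "paired_series")
}
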