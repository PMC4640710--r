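test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(ethnicity_probs = c(white = 0.5, black = 0.4)),
               "ethnicity_probs")
  expect_error(sim_config(diagnosis_probs = c(a = 0.5, b = 0.6)),
               "diagnosis_probs")
  expect_error(sim_config(item_thresholds = c(1.3, 0.25)), "item_thresholds")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(sigma_subject = -1), "sigma_subject")
  expect_error(sim_config(gamma_proximal = c(violent_ideation = 1)),
               "gamma_proximal")
})

test_that("an empty cohort still carries the full item catalogue", {
  panel <- generate_cohort(small_config(n_subjects = 0L))
  expect_s3_class(panel, "cohort_panel")
  expect_identical(nrow(panel$data), 0L)
  expect_identical(panel$catalogue, item_catalogue())
  expect_true(all(item_catalogue()$name %in% names(panel$data)))
})

test_that("the same configuration and seed reproduce the panel exactly", {
  cfg <- small_config(seed = 31L)
  p1 <- generate_cohort(cfg)
  p2 <- generate_cohort(cfg)
  expect_identical(p1$data, p2$data)
  p3 <- generate_cohort(small_config(seed = 32L))
  expect_false(identical(p1$data, p3$data))
})

test_that("with all effects off, window prevalence matches the intercept", {
  # binomial closed form: SE = sqrt(p (1 - p) / n)
  p0 <- 0.14
  n <- 5000L
  cfg <- null_config(n_subjects = n, sigma_subject = 0, rho = 0,
                     retention_m6 = 1, retention_m12 = 1, seed = 41L)
  s <- panel_summary(generate_cohort(cfg))
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(s$violence$prevalence[1] - p0), 3 * se)
  expect_lt(abs(s$violence$prevalence[2] - p0), 3 * se)
})

test_that("covariate distributions track their configured probabilities", {
  n <- 5000L
  cfg <- small_config(n_subjects = n, n_trusts = 26L, seed = 43L)
  s <- panel_summary(generate_cohort(cfg))
  expect_lt(abs(s$covariates$gender[["female"]] - 0.111),
            3 * sqrt(0.111 * 0.889 / n))
  expect_lt(abs(s$covariates$age[["mean"]] - 37.8), 3 * 9.7 / sqrt(n))
  expect_lt(abs(s$covariates$ethnicity[["white"]] - 0.601),
            3 * sqrt(0.601 * 0.399 / n))
})

test_that("with no causal structure every item discriminates at chance", {
  cfg <- null_config(n_subjects = 4000L, retention_m6 = 1, retention_m12 = 1,
                     seed = 47L)
  prox <- build_proximity(generate_cohort(cfg))
  for (item in c("violent_ideation", "self_control", "lack_of_insight")) {
    expect_lt(abs(auc_point(prox[[item]], prox$outcome) - 0.5), 0.04)
  }
})

test_that("historical items never change across waves", {
  panel <- generate_cohort(small_config(seed = 53L))
  d <- panel$data
  for (item in c("violence_history", "traumatic_experiences")) {
    spread <- tapply(d[[item]], d$subject_id, function(x) length(unique(x)))
    expect_true(all(spread == 1L))
  }
})

test_that("near-unit autocorrelation freezes dynamic item ratings", {
  panel <- generate_cohort(small_config(n_subjects = 300L, rho = 0.9999,
                                        retention_m6 = 1, retention_m12 = 1,
                                        seed = 59L))
  d <- panel$data
  changed <- vapply(dynamic_items(panel$catalogue), function(item) {
    mean(tapply(d[[item]], d$subject_id, function(x) length(unique(x)) > 1L))
  }, numeric(1))
  expect_lt(mean(changed), 0.02)
})

test_that("violence prevalence is monotone in the baseline intercept", {
  prevs <- vapply(c(-5, -3.97, -2.5, -1), function(b0) {
    cfg <- small_config(n_subjects = 1500L, baseline_logit = b0, seed = 61L)
    panel_summary(generate_cohort(cfg))$violence$prevalence[1]
  }, numeric(1))
  expect_true(all(diff(prevs) >= 0))
})

test_that("attrition is monotone and matches the configured retention", {
  n <- 5000L
  panel <- generate_cohort(small_config(n_subjects = n, seed = 67L))
  d <- panel$data
  has <- function(w) unique(d$subject_id[d$wave == w])
  m6 <- has("m6"); m12 <- has("m12")
  expect_true(all(m12 %in% m6))  # monotone dropout
  expect_lt(abs(length(m6) / n - 0.95), 3 * sqrt(0.95 * 0.05 / n))
  expect_lt(abs(length(m12) / length(m6) - 0.89),
            3 * sqrt(0.89 * 0.11 / length(m6)))
  # violence flags exist exactly for observed closing waves
  expect_true(all(!is.na(d$violence_w[d$wave != "baseline"])))
  expect_true(all(is.na(d$violence_w[d$wave == "baseline"])))
})

test_that("panel_summary counts windows and completion correctly", {
  panel <- make_panel(
    ratings = list(A = list(baseline = list(), m6 = list(), m12 = list()),
                   B = list(baseline = list(), m6 = list(), m12 = list())),
    violence = list(A = c(w1 = 1L, w2 = 0L), B = c(w1 = 0L, w2 = 0L)))
  s <- panel_summary(panel)
  expect_equal(s$violence$prevalence, c(0.5, 0))
  expect_equal(s$completion$fraction, c(1, 1, 1))

  empty <- generate_cohort(small_config(n_subjects = 0L))
  expect_error(panel_summary(empty), "empty")
})
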