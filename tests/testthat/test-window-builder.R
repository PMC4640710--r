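full_waves <- function(ideation = c(0L, 1L, 2L)) {
  list(baseline = list(violent_ideation = ideation[1]),
       m6 = list(violent_ideation = ideation[2]),
       m12 = list(violent_ideation = ideation[3]))
}

test_that("lagged design pairs prior-wave ratings with each window", {
  panel <- make_panel(list(A = full_waves()),
                      list(A = c(w1 = 0L, w2 = 1L)))
  lag <- build_lagged(panel)
  expect_equal(nrow(lag), 2L)
  expect_equal(lag$outcome[order(lag$window)], c(0L, 1L))
  # exposures from baseline and m6 respectively
  expect_equal(lag$violent_ideation[order(lag$window)], c(0L, 1L))
})

test_that("lagged design drops windows whose waves are unobserved", {
  panel <- make_panel(
    list(A = full_waves()[c("baseline", "m6")]),
    list(A = c(w1 = 0L, w2 = NA)))
  lag <- build_lagged(panel)
  expect_equal(nrow(lag), 1L)
  expect_equal(lag$window, "w1")
})

test_that("proximity design pairs concurrent ratings and outcomes", {
  panel <- make_panel(list(A = full_waves()),
                      list(A = c(w1 = 1L, w2 = 0L)))
  prox <- build_proximity(panel)
  expect_equal(nrow(prox), 2L)
  expect_equal(prox$violent_ideation[order(prox$window)], c(1L, 2L))

  only_base <- make_panel(list(B = full_waves()["baseline"]),
                          list(B = c(w1 = NA, w2 = NA)))
  expect_equal(nrow(build_proximity(only_base)), 0L)
})

test_that("static design repeats baseline historical exposures per window", {
  panel <- make_panel(
    list(A = list(baseline = list(violence_history = 2L),
                  m6 = list(), m12 = list())),
    list(A = c(w1 = 0L, w2 = 1L)))
  st <- build_static(panel)
  expect_equal(nrow(st), 2L)
  expect_equal(st$violence_history, c(2L, 2L))
  expect_setequal(st$outcome, c(0L, 1L))
  expect_false("violent_ideation" %in% names(st))
})

test_that("row counts equal the brute-force recount over the panel", {
  panel <- generate_cohort(small_config(n_subjects = 250L, seed = 13L))
  d <- panel$data
  waves_by_subject <- tapply(d$wave, d$subject_id, identity)
  recount <- function(exposure_wave, outcome_wave) {
    sum(vapply(waves_by_subject, function(w)
      exposure_wave %in% w && outcome_wave %in% w, logical(1)))
  }
  expect_equal(nrow(build_lagged(panel)),
               recount("baseline", "m6") + recount("m6", "m12"))
  expect_equal(nrow(build_proximity(panel)),
               recount("m6", "m6") + recount("m12", "m12"))
  expect_equal(nrow(build_static(panel)),
               recount("baseline", "m6") + recount("baseline", "m12"))
})

test_that("every row's exposures trace back to the design's wave", {
  panel <- generate_cohort(small_config(n_subjects = 120L, seed = 17L))
  d <- panel$data
  lookup <- function(sid, wave, item)
    d[[item]][d$subject_id == sid & d$wave == wave]
  check <- function(ds, wave_of, items) {
    for (i in sample(nrow(ds), min(40, nrow(ds)))) {
      w <- wave_of[[ds$window[i]]]
      for (item in items)
        expect_identical(ds[[item]][i], lookup(ds$subject_id[i], w, item))
    }
  }
  dyn <- c("violent_ideation", "self_control")
  check(build_lagged(panel), list(w1 = "baseline", w2 = "m6"), dyn)
  check(build_proximity(panel), list(w1 = "m6", w2 = "m12"), dyn)
  check(build_static(panel), list(w1 = "baseline", w2 = "baseline"),
        c("violence_history", "violent_attitudes"))
})

test_that("covariates are baseline-fixed across a subject's rows", {
  panel <- generate_cohort(small_config(n_subjects = 150L, seed = 19L))
  for (ds in list(build_lagged(panel), build_proximity(panel))) {
    per_subject <- split(ds[c("age", "gender", "ethnicity", "diagnosis")],
                         ds$subject_id)
    expect_true(all(vapply(per_subject,
                           function(x) nrow(unique(x)) == 1L, logical(1))))
  }
})

test_that("frozen items make lagged and proximity exposures coincide", {
  panel <- generate_cohort(small_config(n_subjects = 200L, rho = 0.9999,
                                        retention_m6 = 1, retention_m12 = 1,
                                        seed = 23L))
  lag <- build_lagged(panel)
  prox <- build_proximity(panel)
  m <- merge(lag, prox, by = c("subject_id", "window"),
             suffixes = c("_lag", "_prox"))
  items <- dynamic_items(panel$catalogue)
  same <- vapply(items, function(item)
    mean(m[[paste0(item, "_lag")]] == m[[paste0(item, "_prox")]]), numeric(1))
  expect_gt(mean(same), 0.98)
  expect_identical(m$outcome_lag, m$outcome_prox)
})

test_that("scale totals are the row sums of their items", {
  panel <- generate_cohort(small_config(n_subjects = 50L, seed = 29L))
  prox <- build_proximity(panel)
  cl_items <- item_catalogue()
  cl <- cl_items$name[cl_items$scale == "C"]
  expect_equal(prox$total_clinical, unname(rowSums(prox[cl])))
  sap <- cl_items$name[cl_items$scale == "SAPROF"]
  expect_equal(prox$total_saprof, unname(rowSums(prox[sap])))
})
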