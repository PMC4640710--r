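# Independent oracles and hand-built fixtures shared across the suite.

# Exhaustive case-control pair counting: the definitional AUC.
brute_auc <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

# Delete-1-observation jackknife SE of the AUC (independent-data oracle).
loo_jackknife_se <- function(scores, outcomes) {
  n <- length(scores)
  loo <- vapply(seq_len(n), function(i) {
    o <- outcomes[-i]
    if (all(o == 1) || all(o == 0)) return(NA_real_)
    brute_auc(scores[-i], o)
  }, numeric(1))
  loo <- loo[!is.na(loo)]
  g <- length(loo)
  sqrt((g - 1) / g * sum((loo - mean(loo))^2))
}

# Build a cohort_panel by hand from per-subject wave/outcome prescriptions.
# ratings: named list subject_id -> list(wave -> named item scores); unstated
# items default to 0. violence: named list subject_id -> c(w1 =, w2 =) (NA for
# unobserved windows).
make_panel <- function(ratings, violence) {
  cat <- item_catalogue()
  rows <- list()
  for (sid in names(ratings)) {
    for (wave in names(ratings[[sid]])) {
      row <- data.frame(subject_id = sid, trust_id = "T01", wave = wave,
                        age = 40, gender = "male", ethnicity = "white",
                        diagnosis = "schizophrenia_spectrum",
                        stringsAsFactors = FALSE)
      for (item in cat$name) {
        v <- ratings[[sid]][[wave]][[item]]
        row[[item]] <- if (is.null(v)) 0L else as.integer(v)
      }
      row$violence_w <- if (wave == "m6") violence[[sid]][["w1"]]
                        else if (wave == "m12") violence[[sid]][["w2"]]
                        else NA_integer_
      rows[[length(rows) + 1L]] <- row
    }
  }
  data <- do.call(rbind, rows)
  proxrisk:::new_cohort_panel(data, cat, "external file")
}

# Reduced-size paper-like configuration for fast simulation tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 200L, n_trusts = 8L, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Null configuration: no causal structure, outcome clustered within subject.
null_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_subjects = 200L, n_trusts = 8L,
    gamma_proximal = c(violent_ideation = 0, instability = 0,
                       stress_coping = 0, self_control = 0),
    delta_distal = 0, sigma_subject = 0.7, sigma_trust = 0,
    baseline_logit = stats::qlogis(0.14), window2_offset = 0, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# One-driver configuration: violence depends on a single modelled item, so a
# single-exposure model is correctly specified and its random-effect variance
# is exactly the configured sigma_subject^2.
one_driver_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_subjects = 600L, n_trusts = 8L, delta_distal = 0,
    gamma_proximal = c(violent_ideation = 1.2, instability = 0,
                       stress_coping = 0, self_control = 0),
    sigma_subject = 0, sigma_trust = 0,
    baseline_logit = -2.2, window2_offset = 0, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Random small score/outcome sets with both classes present.
random_small_dataset <- function(n) {
  repeat {
    scores <- sample(0:2, n, replace = TRUE)
    outcomes <- stats::rbinom(n, 1, 0.5)
    if (any(outcomes == 1) && any(outcomes == 0))
      return(list(scores = scores, outcomes = outcomes))
  }
}

# Wrap bare rows as a model_dataset (one row per subject unless ids given).
as_model_dataset <- function(scores, outcomes, subject_id = NULL,
                             design = "proximity") {
  n <- length(scores)
  if (is.null(subject_id)) subject_id <- sprintf("P%03d", seq_len(n))
  df <- data.frame(subject_id = subject_id, trust_id = "T01",
                   window = "w1", outcome = outcomes, age = 40,
                   gender = "male", ethnicity = "white",
                   diagnosis = "schizophrenia_spectrum", score = scores,
                   stringsAsFactors = FALSE)
  structure(df, design = design,
            n_subjects = length(unique(subject_id)), n_trusts = 1L,
            class = c("model_dataset", "data.frame"))
}
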