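#' Generate a synthetic longitudinal forensic cohort
#'
#' Simulates a panel of subjects nested in Trusts, rated at up to three waves
#' (baseline, 6 months, 12 months) on the HCR-20v3 and SAPROF item sets, with a
#' binary violence outcome for each of the two 6-month follow-up windows. The
#' generative model is described under \code{\link{sim_config}}: latent AR(1)
#' item dynamics cut into ordinal 0/1/2 ratings, distal items tied to proximal
#' items through a shared per-side latent factor, and violence in a window
#' driven only by the proximal item scores at the wave closing that window plus
#' subject and Trust random intercepts. Historical items are drawn once and
#' held constant across waves. Dropout is monotone and missing at random by
#' wave; violence flags exist only for windows whose closing wave is observed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{cohort_panel}: a list with \code{$data} (one row per
#'   subject-by-observed-wave, covariates, item ratings, and \code{violence_w}
#'   carrying the outcome of the window ending at that wave, \code{NA} on
#'   baseline rows), \code{$catalogue} (see \code{\link{item_catalogue}}) and
#'   \code{$config}.
#' @export
#' @examples
#' panel <- generate_cohort(sim_config(n_subjects = 40, n_trusts = 4, seed = 7))
#' panel
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  catalogue <- item_catalogue()
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_subjects
  if (n == 0L) {
    return(new_cohort_panel(empty_panel_data(catalogue), catalogue, config))
  }

  waves <- c("baseline", "m6", "m12")
  subject_id <- sprintf("P%04d", seq_len(n))
  trust_id <- sprintf("T%02d", sample(rep_len(seq_len(config$n_trusts), n)))

  age <- round(stats::rnorm(n, config$age_mean, config$age_sd), 1)
  age <- pmax(age, 18)
  gender <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  ethnicity <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                      prob = config$ethnicity_probs)
  diagnosis <- sample(names(config$diagnosis_probs), n, replace = TRUE,
                      prob = config$diagnosis_probs)

  u_trust_by_trust <- stats::rnorm(config$n_trusts, 0, config$sigma_trust)
  names(u_trust_by_trust) <- sprintf("T%02d", seq_len(config$n_trusts))
  u_trust <- u_trust_by_trust[trust_id]
  u_subj <- stats::rnorm(n, 0, config$sigma_subject)

  # shared per-side latent factors, AR(1) across waves
  ar1 <- function() {
    m <- matrix(NA_real_, n, 3)
    m[, 1] <- stats::rnorm(n)
    for (w in 2:3)
      m[, w] <- config$rho * m[, w - 1] +
        sqrt(1 - config$rho^2) * stats::rnorm(n)
    m
  }
  f_side <- list(risk = ar1(), protective = ar1())

  lam <- config$lambda_proximal
  a_distal <- if (lam > 0) config$delta_distal / lam else 0
  proximal <- c(proximal_risk_items(), proximal_protective_item())

  score_item <- function(z, item) {
    thr <- thresholds_for(config, item)
    (z > thr[1]) + (z > thr[2])
  }

  scores <- list()  # item -> n x 3 matrix of ratings
  for (i in seq_len(nrow(catalogue))) {
    item <- catalogue$name[i]
    if (catalogue$scale[i] == "H") {
      z <- stats::rnorm(n)
      scores[[item]] <- matrix(score_item(z, item), n, 3)
    } else {
      side <- if (catalogue$scale[i] == "SAPROF") "protective" else "risk"
      load <- if (item %in% proximal) lam else a_distal
      z <- load * f_side[[side]] + sqrt(1 - load^2) * ar1()
      scores[[item]] <- matrix(score_item(as.vector(z), item), n, 3)
    }
  }

  # violence per window: logit depends on proximal scores at the closing wave
  violence <- matrix(NA_integer_, n, 2)
  for (k in 1:2) {
    closing <- k + 1L  # w1 closes at m6, w2 closes at m12
    lp <- config$baseline_logit + if (k == 2L) config$window2_offset else 0
    for (item in names(config$gamma_proximal))
      lp <- lp + config$gamma_proximal[[item]] * scores[[item]][, closing]
    lp <- lp + u_subj + u_trust
    violence[, k] <- stats::rbinom(n, 1, stats::plogis(lp))
  }

  obs_m6 <- stats::runif(n) < config$retention_m6
  obs_m12 <- obs_m6 & (stats::runif(n) < config$retention_m12)
  observed <- cbind(baseline = TRUE, m6 = obs_m6, m12 = obs_m12)

  rows <- vector("list", 3L)
  for (w in 1:3) {
    keep <- observed[, w]
    if (!any(keep)) next
    df <- data.frame(subject_id = subject_id[keep], trust_id = trust_id[keep],
                     wave = waves[w], age = age[keep], gender = gender[keep],
                     ethnicity = ethnicity[keep], diagnosis = diagnosis[keep],
                     stringsAsFactors = FALSE)
    for (item in catalogue$name) df[[item]] <- scores[[item]][keep, w]
    df$violence_w <- if (w == 1L) NA_integer_ else violence[keep, w - 1L]
    rows[[w]] <- df
  }
  data <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  data <- data[order(data$subject_id, match(data$wave, waves)), ]
  rownames(data) <- NULL
  new_cohort_panel(data, catalogue, config)
}

new_cohort_panel <- function(data, catalogue, config) {
  structure(list(data = data, catalogue = catalogue, config = config),
            class = "cohort_panel")
}

empty_panel_data <- function(catalogue) {
  base <- data.frame(subject_id = character(), trust_id = character(),
                     wave = character(), age = numeric(), gender = character(),
                     ethnicity = character(), diagnosis = character(),
                     stringsAsFactors = FALSE)
  for (item in catalogue$name) base[[item]] <- integer()
  base$violence_w <- integer()
  base
}

#' @export
print.cohort_panel <- function(x, ...) {
  d <- x$data
  n <- length(unique(d$subject_id))
  cat(sprintf("Cohort panel: %d subjects in %d Trusts, %d subject-wave rows\n",
              n, length(unique(d$trust_id)), nrow(d)))
  for (w in c("baseline", "m6", "m12"))
    cat(sprintf("  %-8s %d rows\n", w, sum(d$wave == w)))
  if (any(d$wave != "baseline")) {
    for (w in c("m6", "m12")) {
      v <- d$violence_w[d$wave == w]
      if (length(v))
        cat(sprintf("  violence in window ending at %s: %.1f%% (%d/%d)\n",
                    w, 100 * mean(v), sum(v), length(v)))
    }
  }
  invisible(x)
}

#' Summarise a cohort panel
#'
#' Computes per-window violence prevalence, wave completion, baseline covariate
#' distributions and pooled per-item rating distributions.
#'
#' @param panel a \code{cohort_panel}.
#' @return An object of class \code{panel_summary} with components
#'   \code{violence} (window, n, cases, prevalence), \code{completion} (wave,
#'   n, fraction of subjects), \code{covariates} (age moments plus category
#'   frequencies) and \code{items} (per-item rating proportions).
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "cohort_panel"))
  d <- panel$data
  if (nrow(d) == 0L) stop("cannot summarise an empty cohort panel", call. = FALSE)

  n_subj <- length(unique(d$subject_id))
  windows <- data.frame(window = c("w1", "w2"), wave = c("m6", "m12"),
                        stringsAsFactors = FALSE)
  violence <- do.call(rbind, lapply(seq_len(2), function(k) {
    v <- d$violence_w[d$wave == windows$wave[k]]
    data.frame(window = windows$window[k], n = length(v), cases = sum(v),
               prevalence = if (length(v)) mean(v) else NA_real_)
  }))
  completion <- do.call(rbind, lapply(c("baseline", "m6", "m12"), function(w) {
    nw <- sum(d$wave == w)
    data.frame(wave = w, n = nw, fraction = nw / n_subj)
  }))
  base <- d[d$wave == "baseline", ]
  if (nrow(base) == 0L) base <- d[!duplicated(d$subject_id), ]
  covariates <- list(
    age = c(mean = mean(base$age), sd = stats::sd(base$age)),
    gender = prop.table(table(base$gender)),
    ethnicity = prop.table(table(base$ethnicity)),
    diagnosis = prop.table(table(base$diagnosis))
  )
  item_names <- panel$catalogue$name
  items <- t(vapply(item_names, function(item) {
    s <- factor(d[[item]], levels = 0:2)
    prop.table(table(s))
  }, numeric(3)))
  colnames(items) <- paste0("p", 0:2)

  structure(list(n_subjects = n_subj, violence = violence,
                 completion = completion, covariates = covariates,
                 items = as.data.frame(items)),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("Panel of %d subjects\n", x$n_subjects))
  cat("Violence prevalence by window:\n")
  print(x$violence, row.names = FALSE)
  cat("Wave completion:\n")
  print(x$completion, row.names = FALSE)
  cat(sprintf("Age %.1f (SD %.1f); female %.1f%%\n",
              x$covariates$age["mean"], x$covariates$age["sd"],
              100 * (if ("female" %in% names(x$covariates$gender))
                x$covariates$gender[["female"]] else 0)))
  invisible(x)
}

#' Calibrate the violence-model intercept to a target prevalence
#'
#' Monte-Carlo search for the \code{baseline_logit} (and, optionally, the
#' second-window offset) at which the simulated window prevalences hit their
#' targets under a given configuration. Used once to freeze the shipped
#' defaults; exposed so alternative effect sizes can be recalibrated.
#'
#' @param config a \code{\link{sim_config}} whose non-intercept parameters are
#'   taken as given.
#' @param target_w1,target_w2 target prevalences for the two windows.
#' @param n_subjects Monte-Carlo cohort size for the calibration run.
#' @param seed seed of the calibration cohort.
#' @return Named numeric vector with elements \code{baseline_logit} and
#'   \code{window2_offset}.
#' @export
calibrate_baseline_logit <- function(config, target_w1 = 0.14,
                                     target_w2 = 0.125,
                                     n_subjects = 200000L, seed = 99L) {
  cfg <- config
  cfg$n_subjects <- as.integer(n_subjects)
  cfg$n_trusts <- max(cfg$n_trusts, 500L)  # average out Trust-level noise
  cfg$retention_m6 <- 1
  cfg$retention_m12 <- 1
  cfg$seed <- seed
  prev <- function(b0, off) {
    cfg$baseline_logit <- b0
    cfg$window2_offset <- off
    p <- generate_cohort(cfg)$data
    c(mean(p$violence_w[p$wave == "m6"]), mean(p$violence_w[p$wave == "m12"]))
  }
  b0 <- stats::uniroot(function(b) prev(b, 0)[1] - target_w1,
                       c(-8, 2), tol = 1e-3)$root
  off <- stats::uniroot(function(o) prev(b0, o)[2] - target_w2,
                        c(-2, 2), tol = 1e-3)$root
  c(baseline_logit = b0, window2_offset = off)
}
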