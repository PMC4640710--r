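#' Simulation configuration for the synthetic forensic cohort
#'
#' Builds and validates the parameter set governing \code{\link{generate_cohort}}.
#' Defaults are calibrated to the published descriptives of a cohort of 409
#' patients discharged from 32 medium secure units in 26 NHS Trusts, followed at
#' 6 and 12 months: mean age 37.8 (SD 9.7), 11.1\% female, ethnicity
#' white/black/South Asian/mixed-or-other = 60.1/25.4/6.2/8.3\%, 80.9\%
#' schizophrenia-spectrum diagnoses, violence prevalence 14.0\% in the first
#' 6-month window and 12.5\% in the second, wave retention 95\% at 6 months and
#' 89\% (of those still followed) at 12 months.
#'
#' The causal structure is distal -> proximal -> violence: each dynamic item has
#' a standard-normal latent value that evolves as an AR(1) process across waves
#' (autocorrelation \code{rho}) and is cut at \code{item_thresholds} into the
#' ordinal 0/1/2 rating. Items on the same side (risk: HCR-20v3 C/R scales;
#' protective: SAPROF) share a per-wave latent factor: proximal items load on it
#' with \code{lambda_proximal} and distal items with
#' \code{delta_distal / lambda_proximal}, so that the latent correlation between
#' any distal and any proximal item on the same side is exactly
#' \code{delta_distal}. Violence in a window depends \emph{only} on the proximal
#' item scores at the wave closing that window (log-odds \code{gamma_proximal}
#' per rating point), plus Gaussian subject and Trust random intercepts; distal
#' items have no direct path to violence.
#'
#' @param n_trusts number of Trusts (level-3 clusters).
#' @param n_subjects number of subjects.
#' @param age_mean,age_sd baseline age distribution (years).
#' @param p_female probability of female gender.
#' @param ethnicity_probs named probability vector over ethnicity categories.
#' @param diagnosis_probs named probability vector over primary diagnoses.
#' @param sigma_subject,sigma_trust SDs of the subject and Trust random
#'   intercepts on the logit scale.
#' @param item_thresholds length-2 increasing cutpoints mapping the latent score
#'   to ratings \{0,1,2\}, or a named list of per-item cutpoints.
#' @param rho wave-to-wave latent autocorrelation, in [0, 1).
#' @param gamma_proximal named log-odds effects (per rating point) of the
#'   proximal items on violence; negative for self-control.
#' @param delta_distal latent correlation between distal and proximal items on
#'   the same side, in [0, lambda_proximal].
#' @param lambda_proximal loading of proximal items on the shared side factor,
#'   in (0, 1].
#' @param baseline_logit intercept of the violence model, calibrated so the
#'   first-window prevalence matches its target under the default effects.
#' @param window2_offset additive log-odds shift for the second window.
#' @param retention_m6 probability that the 6-month wave is observed.
#' @param retention_m12 probability that the 12-month wave is observed given the
#'   6-month wave was (dropout is monotone).
#' @param seed integer RNG seed.
#'
#' @return An object of class \code{sim_config} (a validated named list).
#' @seealso \code{\link{generate_cohort}}, \code{\link{calibrate_baseline_logit}}
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 50, n_trusts = 5, seed = 1)
#' cfg$rho
sim_config <- function(n_trusts = 26,
                       n_subjects = 409,
                       age_mean = 37.8,
                       age_sd = 9.7,
                       p_female = 0.111,
                       ethnicity_probs = c(white = 0.601, black = 0.254,
                                           asian = 0.062, mixed_other = 0.083),
                       diagnosis_probs = c(schizophrenia_spectrum = 0.809,
                                           other = 0.191),
                       sigma_subject = 0.8,
                       sigma_trust = 0.3,
                       item_thresholds = c(0.25, 1.30),
                       rho = 0.35,
                       gamma_proximal = c(violent_ideation = 1.2,
                                          instability = 0.9,
                                          stress_coping = 1.1,
                                          self_control = -1.3),
                       delta_distal = 0.45,
                       lambda_proximal = 0.75,
                       baseline_logit = -3.97,
                       window2_offset = -0.20,
                       retention_m6 = 0.95,
                       retention_m12 = 0.89,
                       seed = 1L) {
  cfg <- list(n_trusts = n_trusts, n_subjects = n_subjects,
              age_mean = age_mean, age_sd = age_sd, p_female = p_female,
              ethnicity_probs = ethnicity_probs,
              diagnosis_probs = diagnosis_probs,
              sigma_subject = sigma_subject, sigma_trust = sigma_trust,
              item_thresholds = item_thresholds, rho = rho,
              gamma_proximal = gamma_proximal, delta_distal = delta_distal,
              lambda_proximal = lambda_proximal,
              baseline_logit = baseline_logit,
              window2_offset = window2_offset,
              retention_m6 = retention_m6, retention_m12 = retention_m12,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg)
    stop(sprintf("invalid sim_config field '%s': %s", field, msg), call. = FALSE)

  for (f in c("n_trusts", "n_subjects")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      stop_cfg(f, "must be a single non-negative integer")
  }
  for (f in c("p_female", "retention_m6", "retention_m12")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop_cfg(f, "must be a probability in [0, 1]")
  }
  for (f in c("ethnicity_probs", "diagnosis_probs")) {
    v <- cfg[[f]]
    if (is.null(names(v)) || any(v < 0))
      stop_cfg(f, "must be a named vector of non-negative probabilities")
    if (abs(sum(v) - 1) > 1e-12)
      stop_cfg(f, sprintf("must sum to 1 (got %.15f)", sum(v)))
  }
  for (f in c("sigma_subject", "sigma_trust")) {
    if (cfg[[f]] < 0) stop_cfg(f, "must be non-negative")
  }
  if (cfg$rho < 0 || cfg$rho >= 1)
    stop_cfg("rho", "must lie in [0, 1)")
  if (cfg$lambda_proximal <= 0 || cfg$lambda_proximal > 1)
    stop_cfg("lambda_proximal", "must lie in (0, 1]")
  if (cfg$delta_distal < 0 || cfg$delta_distal > cfg$lambda_proximal)
    stop_cfg("delta_distal",
             "must lie in [0, lambda_proximal] so item loadings stay in [0, 1]")
  thr <- cfg$item_thresholds
  thr_ok <- function(x) is.numeric(x) && length(x) == 2L && x[1] < x[2]
  if (is.list(thr)) {
    if (!all(vapply(thr, thr_ok, logical(1))))
      stop_cfg("item_thresholds",
               "each item's cutpoints must be 2 strictly increasing numbers")
  } else if (!thr_ok(thr)) {
    stop_cfg("item_thresholds", "cutpoints must be 2 strictly increasing numbers")
  }
  gp <- cfg$gamma_proximal
  expected <- c(proximal_risk_items(), proximal_protective_item())
  if (!all(expected %in% names(gp)))
    stop_cfg("gamma_proximal",
             sprintf("must name all proximal items (%s)",
                     paste(expected, collapse = ", ")))
  if (!is.numeric(cfg$baseline_logit) || length(cfg$baseline_logit) != 1L)
    stop_cfg("baseline_logit", "must be a single number")
  invisible(cfg)
}

# per-item threshold lookup (list configs may override the common cutpoints)
thresholds_for <- function(cfg, item) {
  thr <- cfg$item_thresholds
  if (is.list(thr)) {
    if (!is.null(thr[[item]])) return(thr[[item]])
    if (!is.null(thr[[".default"]])) return(thr[[".default"]])
    stop(sprintf("invalid sim_config field 'item_thresholds': no cutpoints for item '%s'",
                 item), call. = FALSE)
  }
  thr
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d in %d Trusts; waves baseline/m6/m12 (retention %.2f, %.2f)\n",
              x$n_subjects, x$n_trusts, x$retention_m6, x$retention_m12))
  cat(sprintf("  latent AR(1) rho = %.2f; distal-proximal correlation = %.2f\n",
              x$rho, x$delta_distal))
  cat(sprintf("  violence model: intercept %.2f (window 2 offset %.2f), sigma_subject %.2f, sigma_trust %.2f\n",
              x$baseline_logit, x$window2_offset, x$sigma_subject, x$sigma_trust))
  cat("  proximal effects (log-odds per rating point):\n")
  gp <- x$gamma_proximal
  for (nm in names(gp)) cat(sprintf("    %-18s %+.2f\n", nm, gp[[nm]]))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @param config a \code{\link{sim_config}} object.
#' @return \code{read_sim_config} returns a validated \code{sim_config};
#'   \code{write_sim_config} returns \code{path} invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("ethnicity_probs", "diagnosis_probs", "gamma_proximal"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  if (!is.null(raw$item_thresholds) && !is.list(raw$item_thresholds))
    raw$item_thresholds <- as.numeric(raw$item_thresholds)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  for (f in c("ethnicity_probs", "diagnosis_probs", "gamma_proximal"))
    out[[f]] <- as.list(out[[f]])
  yaml::write_yaml(out, path)
  invisible(path)
}
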