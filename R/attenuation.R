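#' Percentage attenuation of a log-odds coefficient
#'
#' The percentage reduction in the baseline association after adjustment,
#' computed on the log-odds scale:
#' \deqn{100 \times (\beta_{unadjusted} - \beta_{adjusted}) / \beta_{unadjusted}}
#' The sign convention carries over to protective (negative-beta) factors, and
#' values above 100 arise when the adjusted odds ratio crosses 1.
#'
#' @param beta_unadjusted,beta_adjusted log-odds (ln OR) coefficients from the
#'   baseline and the adjusted model.
#' @return The percentage change.
#' @export
#' @examples
#' pct_change(log(3.56), log(1.59))  # 63.48
#' pct_change(log(0.21), log(0.65))  # 72.40, protective factor
pct_change <- function(beta_unadjusted, beta_adjusted) {
  if (any(beta_unadjusted == 0))
    stop("attenuation undefined: unadjusted coefficient is 0", call. = FALSE)
  100 * (beta_unadjusted - beta_adjusted) / beta_unadjusted
}

#' Screen candidate explanatory variables
#'
#' A factor qualifies as an explanatory variable when it is associated, at
#' alpha < 0.05, with \emph{both} the violent outcome and the other
#' risk/protective factors. The outcome screen enters all candidates
#' simultaneously in a covariate-adjusted multilevel logistic model (so that
#' only factors with \emph{independent} effects qualify, the "Model 0"
#' procedure); the exposure screen requires a significant pairwise Spearman
#' correlation with at least one other candidate on the pooled design rows.
#'
#' @param panel a \code{cohort_panel}.
#' @param candidate_items item names; defaults to all dynamic items of the
#'   HCR-20v3 C/R scales.
#' @param design design of the outcome screen (the causal question implies
#'   \code{"proximity"}).
#' @param levels,adjust passed to \code{\link{fit_mixed_logit}}.
#' @param alpha significance level of both screens.
#' @return Character vector of screened item names, with attributes
#'   \code{evidence} (per-candidate outcome p, minimum exposure-screen p,
#'   decision) and \code{model0} (the joint fit).
#' @export
screen_explanatory <- function(panel, candidate_items = NULL,
                               design = "proximity", levels = 3,
                               adjust = TRUE, alpha = 0.05) {
  stopifnot(inherits(panel, "cohort_panel"))
  if (is.null(candidate_items))
    candidate_items <- items_of(panel$catalogue, scale = c("C", "R"))
  dataset <- switch(design, lagged = build_lagged(panel),
                    proximity = build_proximity(panel),
                    static = build_static(panel))

  model0 <- suppressWarnings(
    fit_mixed_logit(dataset, candidate_items, adjust = adjust, levels = levels))
  tt <- model0$terms

  evidence <- do.call(rbind, lapply(candidate_items, function(item) {
    p_out <- tt$p[tt$term == item]
    if (length(p_out) == 0L) p_out <- NA_real_  # dropped (collinear/constant)
    others <- setdiff(candidate_items, item)
    p_exp <- vapply(others, function(o) {
      suppressWarnings(stats::cor.test(dataset[[item]], dataset[[o]],
                                       method = "spearman",
                                       exact = FALSE))$p.value
    }, numeric(1))
    data.frame(item = item, p_outcome = p_out,
               p_exposure_min = if (length(p_exp)) min(p_exp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  evidence$selected <- !is.na(evidence$p_outcome) &
    !is.na(evidence$p_exposure_min) &
    evidence$p_outcome < alpha & evidence$p_exposure_min < alpha
  screened <- evidence$item[evidence$selected]
  attr(screened, "evidence") <- evidence
  attr(screened, "model0") <- model0
  screened
}

#' Explanatory-variable attenuation tables
#'
#' Implements the explanatory-variable procedure on a set of base factors that
#' are associated with violence in the baseline causal model: refit each base
#' factor's covariate-adjusted model adding (i) each explanatory variable
#' singly and (ii) all of them jointly, and record the adjusted OR, CI, p and
#' the \code{\link{pct_change}} of the coefficient against its baseline value.
#' The baseline (unadjusted-for-explanatory) coefficient comes from the
#' one-factor adjusted model under the same design, and a "Model 0" table
#' entering base factors and explanatory variables simultaneously is included.
#'
#' @param panel a \code{cohort_panel}.
#' @param base_factors item names whose attenuation is quantified. Factors that
#'   coincide with an explanatory variable are dropped with a message.
#' @param explanatory_variables the screened explanatory set (see
#'   \code{\link{screen_explanatory}}); may be empty, in which case all
#'   percentage changes are 0 by construction.
#' @param design,levels,adjust passed to \code{\link{fit_mixed_logit}}.
#' @param single_models also fit the one-explanatory-at-a-time models; when
#'   \code{FALSE} only the all-variables model is fitted.
#' @return An \code{attenuation_ledger}: list with \code{explanatory_variables},
#'   \code{baseline} (factor, beta, or, ci, p), \code{model0} (joint-entry
#'   table) and \code{models}, a named list of per-model data frames (factor,
#'   adjusted beta/OR/CI/p, pct_change, converged). Non-convergent refits are
#'   flagged, not dropped.
#' @export
attenuation_table <- function(panel, base_factors, explanatory_variables,
                              design = "proximity", levels = 3, adjust = TRUE,
                              single_models = TRUE) {
  stopifnot(inherits(panel, "cohort_panel"))
  dataset <- switch(design, lagged = build_lagged(panel),
                    proximity = build_proximity(panel),
                    static = build_static(panel))
  overlap <- intersect(base_factors, explanatory_variables)
  if (length(overlap)) {
    message("dropping base factor(s) that are themselves explanatory: ",
            paste(overlap, collapse = ", "))
    base_factors <- setdiff(base_factors, explanatory_variables)
  }

  fit_one <- function(terms) {
    tryCatch(suppressWarnings(
      fit_mixed_logit(dataset, terms, adjust = adjust, levels = levels)),
      error = function(e) e)
  }
  term_row <- function(fit, term) {
    if (inherits(fit, "error"))
      return(data.frame(beta = NA_real_, se = NA_real_, or = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                        converged = FALSE))
    tt <- fit$terms[fit$terms$term == term, ]
    data.frame(beta = tt$beta, se = tt$se, or = tt$or, ci_lo = tt$ci_lo,
               ci_hi = tt$ci_hi, p = tt$p, converged = fit$converged)
  }

  baseline <- do.call(rbind, lapply(base_factors, function(f)
    cbind(factor = f, term_row(fit_one(f), f))))

  model0_fit <- fit_one(unique(c(base_factors, explanatory_variables)))
  model0 <- do.call(rbind, lapply(c(base_factors, explanatory_variables),
                                  function(f) cbind(factor = f,
                                                    term_row(model0_fit, f))))

  model_sets <- list()
  if (single_models && length(explanatory_variables))
    for (ev in explanatory_variables)
      model_sets[[paste0("adjusted_for_", ev)]] <- ev
  model_sets[["adjusted_for_all"]] <- explanatory_variables

  models <- lapply(model_sets, function(evs) {
    rows <- lapply(base_factors, function(f) {
      bu <- baseline$beta[baseline$factor == f]
      row <- term_row(fit_one(unique(c(f, evs))), f)
      row$pct_change <- if (is.na(row$beta) || is.na(bu) || bu == 0) NA_real_
                        else pct_change(bu, row$beta)
      cbind(factor = f, row)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  structure(list(design = design,
                 explanatory_variables = explanatory_variables,
                 base_factors = base_factors, baseline = baseline,
                 model0 = model0, models = models),
            class = "attenuation_ledger")
}

#' @export
print.attenuation_ledger <- function(x, ...) {
  cat(sprintf("Attenuation ledger (%s design)\n", x$design))
  cat(sprintf("  explanatory variables: %s\n",
              if (length(x$explanatory_variables))
                paste(x$explanatory_variables, collapse = ", ") else "(none)"))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %s:\n", gsub("_", " ", nm)))
    for (i in seq_len(nrow(m)))
      cat(sprintf("    %-24s AOR %.2f (%.2f-%.2f), P = %s, %% change %.2f%s\n",
                  m$factor[i], m$or[i], m$ci_lo[i], m$ci_hi[i],
                  format.pval(m$p[i], digits = 3), m$pct_change[i],
                  if (isTRUE(m$converged[i])) "" else " [non-convergent]"))
  }
  invisible(x)
}
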