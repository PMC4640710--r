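#' Nested random-intercept logistic regression for windowed violence outcomes
#'
#' Fits the association between exposures and the binary per-window violence
#' outcome with Gaussian random intercepts respecting the longitudinal nesting:
#' repeated windows within subjects (2 levels) or within subjects within Trusts
#' (3 levels). Estimation is maximum likelihood via \code{lme4::glmer}, using
#' adaptive Gauss-Hermite quadrature (default 7 nodes) for the 2-level model;
#' the 3-level model with two nested random intercepts is estimated by the
#' Laplace approximation (the one-node special case), which is the standard
#' fallback for vector-valued random effects. Inference on the fixed effects is
#' Wald throughout (estimate, SE, odds ratio, 95\% CI, two-sided p).
#'
#' When \code{adjust = TRUE} the baseline covariates age, gender, ethnicity and
#' primary diagnosis enter as fixed effects (reference levels: male, white,
#' schizophrenia-spectrum where present). Ordinal 0/1/2 item exposures enter as
#' numeric by default (one log-odds increment per rating point);
#' \code{exposure_coding = "categorical"} enters them as factors instead.
#'
#' @param dataset a \code{model_dataset} (see \code{\link{build_lagged}}).
#' @param exposure_terms character vector of exposure columns fitted jointly.
#' @param adjust include the baseline covariate set as fixed effects.
#' @param levels 2 (subjects) or 3 (subjects within Trusts).
#' @param nAGQ adaptive quadrature nodes for the 2-level model.
#' @param exposure_coding \code{"numeric"} or \code{"categorical"}.
#' @param include_window also enter the follow-up window (first vs second) as a
#'   fixed effect, absorbing secular change in baseline risk between windows.
#' @return An object of class \code{mixed_logit} with components \code{terms}
#'   (data frame: term, beta, se, or, ci_lo, ci_hi, p), \code{var_subject},
#'   \code{var_trust} (0 for 2-level fits), \code{converged}, \code{n_rows},
#'   \code{loglik}, \code{design}, \code{levels}, \code{nAGQ}, \code{messages}
#'   and \code{fit} (the underlying \code{merMod}).
#' @seealso \code{\link{fit_item_table}} for one-model-per-item tables.
#' @export
#' @examples
#' panel <- generate_cohort(sim_config(n_subjects = 150, n_trusts = 8, seed = 4))
#' m <- fit_mixed_logit(build_proximity(panel), "violent_ideation")
#' summary(m)
fit_mixed_logit <- function(dataset, exposure_terms, adjust = TRUE,
                            levels = 3, nAGQ = 7,
                            exposure_coding = c("numeric", "categorical"),
                            include_window = FALSE) {
  stopifnot(inherits(dataset, "model_dataset"))
  exposure_coding <- match.arg(exposure_coding)
  levels <- match.arg(as.character(levels), c("2", "3"))
  levels <- as.integer(levels)
  if (nrow(dataset) == 0L) stop("empty model dataset", call. = FALSE)
  missing_terms <- setdiff(exposure_terms, names(dataset))
  if (length(missing_terms))
    stop(sprintf("exposure column(s) not in dataset: %s",
                 paste(missing_terms, collapse = ", ")), call. = FALSE)
  if (length(unique(dataset$outcome)) < 2L)
    stop("outcome has a single class; model not identifiable", call. = FALSE)

  df <- as.data.frame(dataset)
  df <- prepare_covariates(df)
  if (exposure_coding == "categorical")
    for (term in exposure_terms) df[[term]] <- factor(df[[term]])

  covars <- if (adjust) adjustment_terms(df) else character()
  if (include_window && length(unique(df$window)) > 1L)
    covars <- c(covars, "window")
  rhs <- c(exposure_terms, covars, "(1 | subject_id)",
           if (levels == 3L) "(1 | trust_id)")
  form <- stats::as.formula(paste("outcome ~", paste(rhs, collapse = " + ")))
  use_nAGQ <- if (levels == 3L) 1L else as.integer(nAGQ)

  msgs <- character()
  fit <- withCallingHandlers(
    lme4::glmer(form, data = df, family = stats::binomial(), nAGQ = use_nAGQ,
                control = lme4::glmerControl(optimizer = "nloptwrap")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {  # e.g. lme4's boundary/rank-deficiency notes
      msgs <<- c(msgs, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })

  sm <- summary(fit)$coefficients
  beta <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  terms_tab <- data.frame(term = rownames(sm), beta = beta, se = se,
                          or = exp(beta), ci_lo = exp(beta - 1.96 * se),
                          ci_hi = exp(beta + 1.96 * se),
                          p = 2 * stats::pnorm(-abs(beta / se)),
                          stringsAsFactors = FALSE)
  rownames(terms_tab) <- NULL

  sep <- terms_tab$term[abs(terms_tab$beta) > 10 | terms_tab$se > 10]
  sep <- setdiff(sep, "(Intercept)")
  if (length(sep))
    warning(sprintf("possible separation: extreme estimate for term(s) %s",
                    paste(sep, collapse = ", ")))

  vc <- lme4::VarCorr(fit)
  var_subject <- as.numeric(vc$subject_id[1])
  var_trust <- if (levels == 3L) as.numeric(vc$trust_id[1]) else 0

  # boundary (zero-variance) and rank-deficiency notes are not optimizer
  # failures; the former is a legitimate MLE, the latter is flagged per term
  benign <- "boundary \\(singular\\)|rank deficient"
  conv_msgs <- c(msgs, unlist(fit@optinfo$conv$lme4$messages))
  conv_msgs <- unique(conv_msgs[!grepl(benign, conv_msgs)])
  converged <- length(conv_msgs) == 0L && isTRUE(fit@optinfo$conv$opt == 0)
  if (!converged)
    warning(sprintf("mixed model did not converge cleanly: %s",
                    paste(unique(conv_msgs), collapse = "; ")))

  structure(list(terms = terms_tab, var_subject = var_subject,
                 var_trust = var_trust, converged = converged,
                 n_rows = nrow(df), loglik = as.numeric(stats::logLik(fit)),
                 design = attr(dataset, "design"), levels = levels,
                 nAGQ = use_nAGQ, exposure_terms = exposure_terms,
                 adjusted = adjust, formula = form, messages = msgs,
                 fit = fit),
            class = "mixed_logit")
}

prepare_covariates <- function(df) {
  relevel_if <- function(f, ref) if (ref %in% levels(f)) stats::relevel(f, ref) else f
  df$gender <- relevel_if(factor(df$gender), "male")
  df$ethnicity <- relevel_if(factor(df$ethnicity), "white")
  df$diagnosis <- relevel_if(factor(df$diagnosis), "schizophrenia_spectrum")
  df
}

# drop covariates that are constant in the data (e.g. tiny simulations)
adjustment_terms <- function(df) {
  cand <- c("age", "gender", "ethnicity", "diagnosis")
  cand[vapply(cand, function(v) length(unique(df[[v]])) > 1L, logical(1))]
}

#' @export
print.mixed_logit <- function(x, ...) {
  cat(sprintf("Mixed-effects logistic model (%d-level%s, %s design, nAGQ = %d)\n",
              x$levels, if (x$adjusted) ", covariate-adjusted" else "",
              x$design, x$nAGQ))
  cat(sprintf("  %d rows; logLik %.2f; var(subject) = %.3f%s; converged: %s\n",
              x$n_rows, x$loglik, x$var_subject,
              if (x$levels == 3L) sprintf(", var(Trust) = %.3f", x$var_trust) else "",
              x$converged))
  show <- x$terms[x$terms$term %in% x$exposure_terms, , drop = FALSE]
  if (nrow(show)) {
    cat("  exposures:\n")
    for (i in seq_len(nrow(show)))
      cat(sprintf("    %-24s OR %.2f (%.2f-%.2f), P = %s\n", show$term[i],
                  show$or[i], show$ci_lo[i], show$ci_hi[i],
                  format.pval(show$p[i], digits = 3)))
  }
  invisible(x)
}

#' @export
summary.mixed_logit <- function(object, ...) {
  print(object)
  cat("All fixed effects:\n")
  tab <- object$terms
  tab[, c("beta", "se", "or", "ci_lo", "ci_hi", "p")] <-
    round(tab[, c("beta", "se", "or", "ci_lo", "ci_hi", "p")], 4)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.mixed_logit <- function(object, ...) {
  stats::setNames(object$terms$beta, object$terms$term)
}

#' @export
confint.mixed_logit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$terms$beta - z * object$terms$se,
               object$terms$beta + z * object$terms$se)
  dimnames(out) <- list(object$terms$term,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.mixed_logit <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, type = type, ...))
  stats::predict(object$fit, newdata = prepare_covariates(as.data.frame(newdata)),
                 type = type, allow.new.levels = TRUE, ...)
}

#' @export
residuals.mixed_logit <- function(object, ...) stats::residuals(object$fit, ...)

#' Per-item association tables under a design
#'
#' Fits one covariate-adjusted random-intercept logistic model per item (and
#' per scale total), mirroring the one-row-per-item layout of instrument
#' validation tables (item, AOR, 95\% CI, P). Items whose fit fails are
#' reported with the error message; the remaining items are still fitted.
#'
#' @param panel a \code{cohort_panel}.
#' @param design \code{"lagged"}, \code{"proximity"} or \code{"static"}.
#' @param levels,adjust,nAGQ passed to \code{\link{fit_mixed_logit}}.
#' @param items exposure columns; defaults to every item of the design's scales
#'   plus the scale totals.
#' @return Data frame with one row per item: estimate, Wald inference, variance
#'   components and a convergence flag.
#' @export
fit_item_table <- function(panel, design = c("proximity", "lagged", "static"),
                           levels = 3, adjust = TRUE, nAGQ = 7, items = NULL) {
  design <- match.arg(design)
  dataset <- switch(design, lagged = build_lagged(panel),
                    proximity = build_proximity(panel),
                    static = build_static(panel))
  if (is.null(items)) {
    items <- if (design == "static")
      c(items_of(panel$catalogue, scale = "H"), "total_historical")
    else c(dynamic_items(panel$catalogue), "total_clinical", "total_risk_mgmt",
           "total_saprof")
    items <- intersect(items, names(dataset))
  }
  rows <- lapply(items, function(item) {
    res <- tryCatch(
      suppressWarnings(fit_mixed_logit(dataset, item, adjust = adjust,
                                       levels = levels, nAGQ = nAGQ)),
      error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(item = item, design = design, beta = NA_real_,
                        se = NA_real_, or = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        var_subject = NA_real_, var_trust = NA_real_,
                        converged = FALSE, error = conditionMessage(res),
                        stringsAsFactors = FALSE))
    tt <- res$terms[res$terms$term == item, ]
    if (nrow(tt) == 0L)  # constant or collinear exposure dropped by the fit
      return(data.frame(item = item, design = design, beta = NA_real_,
                        se = NA_real_, or = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_,
                        var_subject = res$var_subject,
                        var_trust = res$var_trust, converged = FALSE,
                        error = "exposure dropped (constant or collinear)",
                        stringsAsFactors = FALSE))
    data.frame(item = item, design = design, beta = tt$beta, se = tt$se,
               or = tt$or, ci_lo = tt$ci_lo, ci_hi = tt$ci_hi, p = tt$p,
               var_subject = res$var_subject, var_trust = res$var_trust,
               converged = res$converged, error = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(item = character(), design = character(),
                      beta = numeric(), se = numeric(), or = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), p = numeric(),
                      var_subject = numeric(), var_trust = numeric(),
                      converged = logical(), error = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summary of pairwise inter-item Spearman correlations
#'
#' Computes all pairwise Spearman correlations between the items of a scale at
#' a wave and summarises them as mean, SD and median, with the count of pairs
#' significant at a Bonferroni-corrected alpha (0.05 divided by the number of
#' testable pairs). Constant items yield undefined correlations; their pairs
#' are excluded from the summary and listed in the result.
#'
#' @param panel a \code{cohort_panel}.
#' @param scale one of \code{"H"}, \code{"C"}, \code{"R"}, \code{"SAPROF"}, or
#'   \code{"CR"} for the pooled dynamic HCR-20v3 scales.
#' @param wave \code{"baseline"}, \code{"m6"} or \code{"m12"}.
#' @return An object of class \code{spearman_summary}: \code{M}, \code{SD},
#'   \code{Md}, \code{n_significant}, \code{n_pairs}, \code{alpha}, the pair
#'   table and any excluded (constant) items.
#' @export
spearman_item_summary <- function(panel, scale = c("CR", "H", "C", "R", "SAPROF"),
                                  wave = c("baseline", "m6", "m12")) {
  stopifnot(inherits(panel, "cohort_panel"))
  scale <- match.arg(scale)
  wave <- match.arg(wave)
  sc <- if (scale == "CR") c("C", "R") else scale
  items <- items_of(panel$catalogue, scale = sc)
  d <- panel$data[panel$data$wave == wave, items, drop = FALSE]
  if (length(items) < 2L || nrow(d) < 3L)
    stop("need at least 2 items and 3 observations at the requested wave",
         call. = FALSE)

  constant <- items[vapply(items, function(i) stats::sd(d[[i]]) == 0, logical(1))]
  usable <- setdiff(items, constant)
  if (length(usable) < 2L)
    stop("fewer than 2 non-constant items; no correlations defined", call. = FALSE)
  pairs <- utils::combn(usable, 2)
  tests <- apply(pairs, 2, function(pr) {
    ct <- suppressWarnings(stats::cor.test(d[[pr[1]]], d[[pr[2]]],
                                           method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  tab <- data.frame(item1 = pairs[1, ], item2 = pairs[2, ],
                    rho = tests["rho", ], p = tests["p", ],
                    stringsAsFactors = FALSE)
  n_pairs <- nrow(tab)
  alpha <- 0.05 / n_pairs
  structure(list(scale = scale, wave = wave, M = mean(tab$rho),
                 SD = stats::sd(tab$rho), Md = stats::median(tab$rho),
                 n_significant = sum(tab$p < alpha), n_pairs = n_pairs,
                 alpha = alpha, pairs = tab, excluded_items = constant),
            class = "spearman_summary")
}

#' @export
print.spearman_summary <- function(x, ...) {
  cat(sprintf("Spearman correlations, scale %s at %s: M %.2f, SD %.2f, Md %.2f; %d # %d significant (Bonferroni alpha %.2g)\n",
              x$scale, x$wave, x$M, x$SD, x$Md, x$n_significant, x$n_pairs,
              x$alpha))
  if (length(x$excluded_items))
    cat(sprintf("  excluded constant item(s): %s\n",
                paste(x$excluded_items, collapse = ", ")))
  invisible(x)
}
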