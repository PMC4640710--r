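#' Rank-based AUC (Somers' D) point estimate
#'
#' Estimates the probability that a randomly drawn violent case scores higher
#' than a randomly drawn non-violent control, counting ties as one half:
#' \deqn{AUC = P(s_{case} > s_{control}) + \tfrac12 P(s_{case} = s_{control})}
#' which equals \eqn{(D + 1)/2} for Somers' D. Computed from midranks, so it is
#' exact under heavy ties (ordinal 0/1/2 ratings). Values below 0.5 indicate
#' inverse (protective) discrimination.
#'
#' @param scores numeric exposure scores.
#' @param outcomes binary outcomes (0/1), same length.
#' @return The AUC, a probability in [0, 1].
#' @export
#' @examples
#' auc_point(c(2, 2, 0, 0), c(1, 1, 0, 0))  # perfect separation: 1
#' auc_point(c(0, 1, 1, 2, 2), c(0, 0, 1, 0, 1))
auc_point <- function(scores, outcomes) {
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]
  outcomes <- outcomes[keep]
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary 0/1", call. = FALSE)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need at least one case and one control", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Clustered AUC with cluster-jackknife inference
#'
#' Point estimate as \code{\link{auc_point}} on the pooled rows of a
#' \code{model_dataset}; the standard error respects the nesting of repeated
#' windows within subjects by a leave-one-subject-out (delete-1-cluster)
#' jackknife. The 95\% CI is the normal approximation on the AUC scale,
#' truncated to [0, 1]; the p-value tests AUC = 0.5 by the same approximation.
#'
#' @param dataset a \code{model_dataset} (see \code{\link{build_lagged}}).
#' @param item exposure column name (an item or a scale total).
#' @return An \code{auc_result} with fields \code{item}, \code{design},
#'   \code{auc}, \code{se}, \code{ci_lo}, \code{ci_hi}, \code{p},
#'   \code{n_pairs} (case-control pair count) and \code{n_clusters}. With fewer
#'   than 2 subject clusters the point estimate is returned with \code{NA}
#'   inference and a warning.
#' @export
#' @examples
#' panel <- generate_cohort(sim_config(n_subjects = 120, n_trusts = 6, seed = 3))
#' auc_clustered(build_proximity(panel), "violent_ideation")
auc_clustered <- function(dataset, item) {
  stopifnot(inherits(dataset, "model_dataset"))
  if (!item %in% names(dataset))
    stop(sprintf("unknown exposure column '%s'", item), call. = FALSE)
  scores <- dataset[[item]]
  outcomes <- dataset$outcome
  est <- auc_point(scores, outcomes)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)

  clusters <- unique(dataset$subject_id)
  g <- length(clusters)
  if (g < 2L) {
    warning("fewer than 2 subject clusters: returning point estimate without CI")
    return(new_auc_result(item, attr(dataset, "design"), est, NA_real_,
                          NA_real_, NA_real_, NA_real_, n1 * n0, g))
  }
  loo <- vapply(clusters, function(cl) {
    keep <- dataset$subject_id != cl
    o <- outcomes[keep]
    if (all(o == 1) || all(o == 0)) return(NA_real_)
    auc_point(scores[keep], o)
  }, numeric(1))
  if (anyNA(loo)) {
    warning(sprintf("%d leave-one-subject-out replicates undefined (single discordant cluster); dropped from the jackknife",
                    sum(is.na(loo))))
    loo <- loo[!is.na(loo)]
    g <- length(loo)
  }
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  ci <- pmin(pmax(est + c(-1, 1) * 1.96 * se, 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs(est - 0.5) / se) else NA_real_
  new_auc_result(item, attr(dataset, "design"), est, se, ci[1], ci[2], p,
                 n1 * n0, length(clusters))
}

new_auc_result <- function(item, design, auc, se, ci_lo, ci_hi, p, n_pairs,
                           n_clusters) {
  structure(list(item = item, design = design, auc = auc, se = se,
                 ci_lo = ci_lo, ci_hi = ci_hi, p = p, n_pairs = n_pairs,
                 n_clusters = n_clusters),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("%s (%s design): AUC %.3f, 95%% CI %.3f-%.3f, P = %s (%d clusters, %d pairs)\n",
              x$item, x$design, x$auc, x$ci_lo, x$ci_hi, format.pval(x$p, digits = 3),
              x$n_clusters, x$n_pairs))
  invisible(x)
}

#' Compare two AUC estimates by confidence-interval overlap
#'
#' Declares two discrimination estimates \code{"distinct"} only when their 95\%
#' confidence intervals are disjoint; intervals that merely touch at an
#' endpoint count as \code{"overlapping"} (the conservative reading of a
#' non-overlap criterion).
#'
#' @param a,b \code{auc_result} objects carrying CIs.
#' @return \code{"distinct"} or \code{"overlapping"}.
#' @export
compare_auc <- function(a, b) {
  stopifnot(inherits(a, "auc_result"), inherits(b, "auc_result"))
  if (anyNA(c(a$ci_lo, a$ci_hi, b$ci_lo, b$ci_hi)))
    stop("both results must carry confidence intervals", call. = FALSE)
  if (a$ci_hi < b$ci_lo || b$ci_hi < a$ci_lo) "distinct" else "overlapping"
}

#' Per-item AUC table for a model dataset
#'
#' Runs \code{\link{auc_clustered}} over a set of exposure columns, returning a
#' table mirroring the usual instrument-validation layout (item, AUC, 95\% CI,
#' P).
#'
#' @param dataset a \code{model_dataset}.
#' @param items exposure columns; default all items and totals in the dataset.
#' @return Data frame with one row per item.
#' @export
auc_table <- function(dataset, items = exposure_columns(dataset)) {
  rows <- lapply(items, function(item) {
    r <- tryCatch(auc_clustered(dataset, item), error = function(e) NULL)
    if (is.null(r))
      return(data.frame(item = item, design = attr(dataset, "design"),
                        auc = NA_real_, se = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_, n_pairs = NA_integer_))
    data.frame(item = r$item, design = r$design, auc = r$auc, se = r$se,
               ci_lo = r$ci_lo, ci_hi = r$ci_hi, p = r$p, n_pairs = r$n_pairs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
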