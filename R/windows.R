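#' Build exposure-outcome datasets under the competing designs
#'
#' Restructures a \code{cohort_panel} into long-format model datasets pairing
#' item ratings (exposures) with the binary violence outcome of a 6-month
#' window, under three designs:
#' \describe{
#'   \item{lagged (predictive)}{ratings covering the \emph{previous} 6 months
#'     predict violence in the following window: baseline ratings pair with the
#'     first window (0-6 months), 6-month ratings with the second (6-12
#'     months). A row is emitted only when both the exposure wave and the
#'     outcome window's closing wave are observed.}
#'   \item{proximity (causal)}{ratings and outcome from the \emph{same} window:
#'     6-month ratings pair with the first window, 12-month ratings with the
#'     second.}
#'   \item{static}{baseline historical ratings pair with every observed outcome
#'     window (repeated rows per subject).}
#' }
#' Covariates (age, gender, ethnicity, diagnosis) are taken at baseline and
#' repeated across a subject's rows. Besides the individual items, per-scale
#' total scores are added: \code{total_historical}, \code{total_clinical},
#' \code{total_risk_mgmt} (HCR-20v3 H/C/R) and \code{total_saprof}.
#'
#' @param panel a \code{cohort_panel}.
#' @return A \code{model_dataset}: a data frame with one row per subject-window
#'   (columns \code{subject_id}, \code{trust_id}, \code{window},
#'   \code{outcome}, covariates, items, totals) and attributes \code{design},
#'   \code{n_subjects}, \code{n_trusts}.
#' @export
#' @examples
#' panel <- generate_cohort(sim_config(n_subjects = 30, n_trusts = 3, seed = 2))
#' nrow(build_lagged(panel))
#' nrow(build_proximity(panel))
build_lagged <- function(panel) {
  build_design(panel, design = "lagged",
               pairing = data.frame(window = c("w1", "w2"),
                                    exposure_wave = c("baseline", "m6"),
                                    outcome_wave = c("m6", "m12")))
}

#' @rdname build_lagged
#' @export
build_proximity <- function(panel) {
  build_design(panel, design = "proximity",
               pairing = data.frame(window = c("w1", "w2"),
                                    exposure_wave = c("m6", "m12"),
                                    outcome_wave = c("m6", "m12")))
}

#' @rdname build_lagged
#' @export
build_static <- function(panel) {
  build_design(panel, design = "static",
               pairing = data.frame(window = c("w1", "w2"),
                                    exposure_wave = c("baseline", "baseline"),
                                    outcome_wave = c("m6", "m12")))
}

build_design <- function(panel, design, pairing) {
  stopifnot(inherits(panel, "cohort_panel"))
  d <- panel$data
  if (nrow(d) == 0L) stop("cannot build a design from an empty panel",
                          call. = FALSE)
  catalogue <- panel$catalogue
  items <- if (design == "static") items_of(catalogue, scale = "H")
           else catalogue$name
  covars <- c("age", "gender", "ethnicity", "diagnosis")

  key <- function(w) paste(d$subject_id, d$wave)[d$wave == w]
  rows <- vector("list", nrow(pairing))
  base <- d[d$wave == "baseline", c("subject_id", covars)]
  for (k in seq_len(nrow(pairing))) {
    ew <- pairing$exposure_wave[k]
    ow <- pairing$outcome_wave[k]
    exp_rows <- d[d$wave == ew, , drop = FALSE]
    out_rows <- d[d$wave == ow, c("subject_id", "violence_w"), drop = FALSE]
    m <- merge(exp_rows[c("subject_id", "trust_id", items)], out_rows,
               by = "subject_id")
    if (nrow(m) == 0L) next
    m <- merge(m, base, by = "subject_id")
    m$window <- pairing$window[k]
    m$outcome <- as.integer(m$violence_w)
    m$violence_w <- NULL
    rows[[k]] <- m
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- d[0, c("subject_id", "trust_id", items, covars)]
    out$window <- character()
    out$outcome <- integer()
  }
  out <- out[c("subject_id", "trust_id", "window", "outcome", covars, items)]
  out <- add_scale_totals(out, catalogue, items)
  out <- out[order(out$subject_id, out$window), ]
  rownames(out) <- NULL
  structure(out, design = design,
            n_subjects = length(unique(out$subject_id)),
            n_trusts = length(unique(out$trust_id)),
            class = c("model_dataset", "data.frame"))
}

add_scale_totals <- function(df, catalogue, items) {
  totals <- c(H = "total_historical", C = "total_clinical",
              R = "total_risk_mgmt", SAPROF = "total_saprof")
  for (sc in names(totals)) {
    sc_items <- intersect(items_of(catalogue, scale = sc), items)
    if (length(sc_items))
      df[[totals[[sc]]]] <- rowSums(df[, sc_items, drop = FALSE])
  }
  df
}

#' @export
print.model_dataset <- function(x, ...) {
  cat(sprintf("Model dataset (%s design): %d rows, %d subjects, %d Trusts; %d violent\n",
              attr(x, "design"), nrow(x), attr(x, "n_subjects"),
              attr(x, "n_trusts"), sum(x$outcome)))
  invisible(x)
}

# exposure columns available in a dataset (items + totals)
exposure_columns <- function(dataset) {
  setdiff(names(dataset), c("subject_id", "trust_id", "window", "outcome",
                            "age", "gender", "ethnicity", "diagnosis"))
}
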