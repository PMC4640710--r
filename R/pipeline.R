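#' Run the full lagged-versus-proximity comparison pipeline
#'
#' One-call orchestration of the whole analysis in its natural order: simulate
#' (or read) a cohort panel, summarise it, build the lagged and
#' temporal-proximity designs, estimate clustered per-item AUCs under both,
#' fit per-item multilevel association models under both, summarise inter-item
#' Spearman correlations, screen explanatory variables on the proximity design
#' and produce the attenuation ledgers for the risk (HCR-20v3 C/R) and
#' protective (SAPROF) sides. Every stage is logged; stage failures are
#' recorded in the log and leave the corresponding slot \code{NULL} rather than
#' aborting the bundle.
#'
#' @param config a \code{\link{sim_config}}; its \code{seed} makes the bundle
#'   fully reproducible.
#' @param panel optional pre-built \code{cohort_panel} or path to a panel CSV;
#'   when supplied the simulation stage is skipped.
#' @param items optional subset of item names to analyse (totals are always
#'   included); mainly for reduced-size runs.
#' @param levels nesting depth of the association models (AUCs are always
#'   2-level by construction).
#' @param attenuation_single_models fit the one-explanatory-at-a-time
#'   attenuation models in addition to the all-variables model.
#' @return A \code{report_bundle}: config and seed snapshot, panel summary, AUC
#'   and fit tables per design, Spearman summaries, screened explanatory sets,
#'   attenuation ledgers for both sides, and the run log (stage, status,
#'   seconds).
#' @seealso \code{\link{write_bundle}}, \code{\link{render_comparison_figures}}
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(n_subjects = 120, n_trusts = 6, seed = 11)
#' bundle <- run_full_analysis(cfg, items = c("violent_ideation", "lack_of_insight"))
#' bundle
#' }
run_full_analysis <- function(config, panel = NULL, items = NULL, levels = 3,
                              attenuation_single_models = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  log <- data.frame(stage = character(), status = character(),
                    seconds = numeric(), note = character(),
                    stringsAsFactors = FALSE)
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    log <<- rbind(log, data.frame(
      stage = name, status = if (ok) "ok" else "error",
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      note = if (ok) "" else conditionMessage(res), stringsAsFactors = FALSE))
    if (ok) res else NULL
  }

  panel <- run_stage("panel", {
    if (is.null(panel)) generate_cohort(config)
    else if (is.character(panel)) read_panel(panel)
    else panel
  })
  if (is.null(panel)) stop("panel stage failed; see bundle log", call. = FALSE)

  dyn <- dynamic_items(panel$catalogue)
  if (!is.null(items)) dyn <- intersect(dyn, items)
  tot <- c("total_clinical", "total_risk_mgmt", "total_saprof")
  analysis_items <- c(dyn, tot)

  summary_ <- run_stage("panel_summary", panel_summary(panel))
  lagged <- run_stage("build_lagged", build_lagged(panel))
  proximity <- run_stage("build_proximity", build_proximity(panel))

  auc_tables <- list(
    lagged = run_stage("auc_lagged",
                       auc_table(lagged, intersect(analysis_items, names(lagged)))),
    proximity = run_stage("auc_proximity",
                          auc_table(proximity, intersect(analysis_items,
                                                         names(proximity)))))
  fit_tables <- list(
    lagged = run_stage("fit_lagged",
                       fit_item_table(panel, "lagged", levels = levels,
                                      items = intersect(analysis_items,
                                                        names(lagged)))),
    proximity = run_stage("fit_proximity",
                          fit_item_table(panel, "proximity", levels = levels,
                                         items = intersect(analysis_items,
                                                           names(proximity)))))

  spearman <- run_stage("spearman", {
    grids <- list(c("CR", "m6"), c("CR", "m12"), c("SAPROF", "m6"),
                  c("SAPROF", "m12"))
    out <- lapply(grids, function(g)
      tryCatch(spearman_item_summary(panel, g[1], g[2]),
               error = function(e) NULL))
    names(out) <- vapply(grids, paste, character(1), collapse = "_")
    out
  })

  risk_items <- intersect(items_of(panel$catalogue, scale = c("C", "R")), dyn)
  prot_items <- intersect(items_of(panel$catalogue, scale = "SAPROF"), dyn)

  screened_risk <- run_stage("screen_risk",
    screen_explanatory(panel, risk_items, levels = levels))
  screened_prot <- run_stage("screen_protective",
    screen_explanatory(panel, prot_items, levels = levels))

  significant_base <- function(side_items, fits) {
    if (is.null(fits)) return(character())
    f <- fits[fits$item %in% side_items & !is.na(fits$p) & fits$p < 0.05, ]
    f$item
  }
  attenuation <- list(
    risk = run_stage("attenuation_risk", {
      base <- significant_base(risk_items, fit_tables$proximity)
      attenuation_table(panel, base, as.character(screened_risk),
                        levels = levels,
                        single_models = attenuation_single_models)
    }),
    protective = run_stage("attenuation_protective", {
      base <- significant_base(prot_items, fit_tables$proximity)
      attenuation_table(panel, base, as.character(screened_prot),
                        levels = levels,
                        single_models = attenuation_single_models)
    }))

  structure(list(config = config, seed = config$seed, panel = panel,
                 summary = summary_, auc = auc_tables, fits = fit_tables,
                 spearman = spearman,
                 screened = list(risk = screened_risk,
                                 protective = screened_prot),
                 attenuation = attenuation, log = log),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Analysis bundle (seed %s)\n", x$seed))
  print(x$log, row.names = FALSE)
  if (!is.null(x$summary)) {
    cat("\n")
    print(x$summary)
  }
  invisible(x)
}

#' Write a report bundle's tables to CSV
#'
#' Serialises every table of a bundle (panel summary, AUC tables, fit tables,
#' Spearman summaries, attenuation ledgers, run log) as CSV files under a
#' directory, so a bundle can be compared byte-for-byte across runs.
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$summary)) {
    emit(bundle$summary$violence, "violence_prevalence")
    emit(bundle$summary$completion, "wave_completion")
    emit(cbind(item = rownames(bundle$summary$items), bundle$summary$items),
         "item_distributions")
  }
  for (d in names(bundle$auc)) emit(bundle$auc[[d]], paste0("auc_", d))
  for (d in names(bundle$fits)) emit(bundle$fits[[d]], paste0("fits_", d))
  if (!is.null(bundle$spearman)) {
    sp <- do.call(rbind, lapply(Filter(Negate(is.null), bundle$spearman),
      function(s) data.frame(scale = s$scale, wave = s$wave, M = s$M,
                             SD = s$SD, Md = s$Md,
                             n_significant = s$n_significant,
                             n_pairs = s$n_pairs)))
    emit(sp, "spearman_summary")
  }
  for (side in names(bundle$attenuation)) {
    led <- bundle$attenuation[[side]]
    if (is.null(led)) next
    emit(led$baseline, paste0("attenuation_", side, "_baseline"))
    emit(led$model0, paste0("attenuation_", side, "_model0"))
    for (nm in names(led$models))
      emit(led$models[[nm]], paste0("attenuation_", side, "_", nm))
  }
  emit(bundle$log, "run_log")
  invisible(paths)
}

#' Paired bar charts comparing the lagged and proximity designs
#'
#' Renders, for the AUC tables and for the association (OR) tables of a bundle,
#' a paired bar chart per item — white bars for the lagged/predictive design,
#' grey bars for the temporal-proximity/causal design — with 95\% CI error
#' bars. Each figure's plotted values are also written as a CSV data file so
#' the rendering can be audited against the tables it came from. A figure whose
#' design tables are missing is skipped with a log message.
#'
#' @param bundle a \code{report_bundle}.
#' @param dir output directory.
#' @param format \code{"png"} or \code{"svg"}.
#' @return Invisibly, a character vector of files written.
#' @export
render_comparison_figures <- function(bundle, dir, format = c("png", "svg")) {
  stopifnot(inherits(bundle, "report_bundle"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()

  render_one <- function(tabs, value, ref, name, ylab) {
    if (is.null(tabs$lagged) || is.null(tabs$proximity) ||
        !nrow(tabs$lagged) || !nrow(tabs$proximity)) {
      message(sprintf("figure '%s' skipped: missing design table", name))
      return()
    }
    m <- merge(tabs$lagged, tabs$proximity, by = "item",
               suffixes = c("_lagged", "_proximity"))
    m <- m[stats::complete.cases(m[paste0(value, c("_lagged", "_proximity"))]), ]
    if (!nrow(m)) {
      message(sprintf("figure '%s' skipped: no plottable rows", name))
      return()
    }
    data_path <- file.path(dir, paste0(name, "_data.csv"))
    utils::write.csv(m, data_path, row.names = FALSE)

    fig_path <- file.path(dir, paste0(name, ".", format))
    if (format == "png") grDevices::png(fig_path, width = 1400, height = 700)
    else grDevices::svg(fig_path, width = 14, height = 7)
    on.exit(grDevices::dev.off(), add = TRUE)
    heights <- t(as.matrix(m[paste0(value, c("_lagged", "_proximity"))]))
    graphics::par(mar = c(10, 4, 2, 1))  # device-local; dies with dev.off()
    ylim <- c(0, max(m[[paste0("ci_hi_lagged")]],
                     m[[paste0("ci_hi_proximity")]], na.rm = TRUE) * 1.05)
    bp <- graphics::barplot(heights, beside = TRUE,
                            col = c("white", "grey60"),
                            names.arg = m$item, las = 2, ylab = ylab,
                            ylim = ylim,
                            legend.text = c("lagged/predictive",
                                            "proximity/causal"),
                            args.legend = list(x = "topright", bty = "n"))
    for (k in 1:2) {
      sfx <- c("_lagged", "_proximity")[k]
      graphics::arrows(bp[k, ], m[[paste0("ci_lo", sfx)]],
                       bp[k, ], m[[paste0("ci_hi", sfx)]],
                       angle = 90, code = 3, length = 0.03)
    }
    if (!is.null(ref)) graphics::abline(h = ref, lty = 2)
    written <<- c(written, data_path, fig_path)
  }

  render_one(bundle$auc, "auc", 0.5, "fig_auc_comparison", "AUC")
  render_one(bundle$fits, "or", 1, "fig_or_comparison", "Adjusted odds ratio")
  invisible(written)
}
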