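#' Read and write cohort panels as CSV
#'
#' The on-disk schema is one row per subject-by-wave with columns
#' \code{subject_id, trust_id, wave, age, gender, ethnicity, diagnosis},
#' one column per item (ratings in \{0,1,2\}) and \code{violence_w} (the binary
#' outcome of the 6-month window ending at that wave; empty on baseline rows).
#' A YAML sidecar (\code{<path>.yaml} by default) stores the item catalogue and,
#' for simulated panels, the generating configuration, so a written panel can be
#' re-read without loss.
#'
#' @param panel a \code{cohort_panel}.
#' @param path CSV file path.
#' @param sidecar path of the YAML sidecar; \code{NULL} suppresses it on write
#'   and falls back to the built-in catalogue on read.
#' @return \code{write_panel} returns \code{path} invisibly; \code{read_panel}
#'   returns a \code{cohort_panel}.
#' @export
write_panel <- function(panel, path, sidecar = paste0(path, ".yaml")) {
  stopifnot(inherits(panel, "cohort_panel"))
  utils::write.csv(panel$data, path, row.names = FALSE, na = "")
  if (!is.null(sidecar)) {
    meta <- list(item_catalogue = lapply(seq_len(nrow(panel$catalogue)),
      function(i) as.list(panel$catalogue[i, ])))
    if (inherits(panel$config, "sim_config")) {
      cfg <- unclass(panel$config)
      for (f in c("ethnicity_probs", "diagnosis_probs", "gamma_proximal"))
        cfg[[f]] <- as.list(cfg[[f]])
      meta$sim_config <- cfg
    } else {
      meta$provenance <- "external file"
    }
    yaml::write_yaml(meta, sidecar)
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, sidecar = paste0(path, ".yaml")) {
  if (!file.exists(path)) stop(sprintf("panel file not found: %s", path),
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)

  catalogue <- item_catalogue()
  config <- "external file"
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$item_catalogue))
      catalogue <- do.call(rbind, lapply(meta$item_catalogue, as.data.frame))
    if (!is.null(meta$sim_config)) {
      raw <- meta$sim_config
      for (f in c("ethnicity_probs", "diagnosis_probs", "gamma_proximal"))
        if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
      if (!is.null(raw$item_thresholds) && !is.list(raw$item_thresholds))
        raw$item_thresholds <- as.numeric(raw$item_thresholds)
      config <- do.call(sim_config, raw)
    }
  }

  required <- c("subject_id", "trust_id", "wave", "age", "gender",
                "ethnicity", "diagnosis", "violence_w")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop(sprintf("panel schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)

  item_cols <- setdiff(names(d), required)
  unknown <- setdiff(item_cols, catalogue$name)
  if (length(unknown))
    stop(sprintf("panel schema error: unknown item column(s) %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)

  bad_wave <- which(!d$wave %in% c("baseline", "m6", "m12"))
  if (length(bad_wave))
    stop(sprintf("panel schema error: row %d has unknown wave '%s'",
                 bad_wave[1], d$wave[bad_wave[1]]), call. = FALSE)

  for (item in item_cols) {
    bad <- which(!(d[[item]] %in% c(0L, 1L, 2L)))
    if (length(bad))
      stop(sprintf("panel schema error: row %d has score '%s' outside {0,1,2} in item '%s'",
                   bad[1], d[[item]][bad[1]], item), call. = FALSE)
  }

  dup <- which(duplicated(d[c("subject_id", "wave")]))
  if (length(dup))
    stop(sprintf("panel schema error: row %d duplicates subject '%s' at wave '%s'",
                 dup[1], d$subject_id[dup[1]], d$wave[dup[1]]), call. = FALSE)

  follow <- d$wave != "baseline"
  bad_v <- which(follow & !(d$violence_w %in% c(0L, 1L)))
  if (length(bad_v))
    stop(sprintf("panel schema error: row %d has violence_w '%s' (must be 0/1 on follow-up rows)",
                 bad_v[1], d$violence_w[bad_v[1]]), call. = FALSE)
  d$violence_w[!follow] <- NA_integer_

  d <- d[order(d$subject_id, match(d$wave, c("baseline", "m6", "m12"))), ]
  rownames(d) <- NULL
  new_cohort_panel(d, catalogue, config)
}
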