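## End-to-end pipeline: qc -> fa -> screen -> association, with TSV/JSON
## artifacts and a run log. All stages are deterministic given inputs and
## configuration; reruns produce byte-identical numeric outputs.

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline. Each threshold is serialized into
#' the provenance header of every output artifact and into the run log.
#'
#' @param alpha Significance level on Holm-adjusted p-values (default 0.05).
#' @param qc A [qc_control()].
#' @param min_n Minimum individuals for a viable genotype (default 10).
#' @param mode [compare_fa()] test mode.
#' @param col_map Optional column mapping for [read_measurements()].
#' @param seed Integer recorded in the run log (the pipeline itself draws
#'   no random numbers; the seed documents any upstream simulation).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, qc = qc_control(), min_n = 10L,
                            mode = c("interaction", "fa10a"),
                            col_map = NULL, seed = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, inherits(qc, "qc_control"), min_n >= 2)
  structure(list(alpha = alpha, qc = qc, min_n = as.integer(min_n),
                 mode = mode, col_map = col_map, seed = seed),
            class = "pipeline_config")
}

provenance_header <- function(config) {
  c(paste0("# wingFA ", as.character(utils::packageVersion("wingFA"))),
    paste0("# alpha=", config$alpha,
           " alpha_norm=", config$qc$alpha_norm,
           " g1_bound=", config$qc$g1_bound,
           " g2_bound=", config$qc$g2_bound,
           " max_removals=", config$qc$max_removals,
           " qc_min_n=", config$qc$min_n,
           " min_n=", config$min_n,
           " mode=", config$mode,
           " seed=", config$seed))
}

write_tsv_artifact <- function(x, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline artifact TSV
#'
#' @param path Path written by [run_pipeline()] (provenance header lines
#'   start with `#` and are skipped).
#' @return A `data.frame`.
#' @export
read_tsv_artifact <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

qc_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(q)
    data.frame(genotype = q$genotype, series = q$series,
               n_initial = q$n_initial, n_final = q$n_final,
               removed_ids = paste(q$removed_ids, collapse = ","),
               shapiro_p = q$shapiro_p, lilliefors_p = q$lilliefors_p,
               g1 = q$g1, g2 = q$g2, pass = q$pass,
               flags = paste(q$flags, collapse = ";"),
               stringsAsFactors = FALSE)))
}

#' Run the full FA screen pipeline
#'
#' Executes qc -> fa -> screen -> association on a measurement dataset and
#' writes the artifact files: `qc_report.tsv`, `fa_results.tsv`,
#' `screen_primary.tsv`, `screen_secondary.tsv` (when secondary layouts are
#' given), `confirmed_modifiers.tsv`, `associations.tsv`, and
#' `run_log.json`. Fatal errors carry their pipeline stage in the message.
#'
#' @param measurements A measurement `data.frame` or a file path readable
#'   by [read_measurements()].
#' @param primary_layouts List of [series_layout()] for the primary stage.
#' @param secondary_layouts Optional list of layouts for the secondary
#'   stage (with negative controls and `df_alone` maps).
#' @param out_dir Output directory (created if missing); `NULL` writes no
#'   files.
#' @param config A [pipeline_config()].
#' @param deficiencies Optional deficiency metadata (see
#'   [read_deficiencies()]) used for the fold-change vs span correlation.
#' @return Invisibly, a list: `samples`, `qc`, `fits`, `summaries`,
#'   `primary`, `secondary`, `aggregate`, `associations`, `log`.
#' @examples
#' scn <- screen_scenario(n_series = 1, per_series = 3, seed = 5,
#'                        baseline = sim_config(n = 12))
#' sim <- simulate_screen(scn)
#' meas <- do.call(rbind, lapply(sim$samples, function(s) s$data))
#' res <- run_pipeline(meas, sim$layouts, out_dir = NULL,
#'                     config = pipeline_config(min_n = 10))
#' res$primary
#' @export
run_pipeline <- function(measurements, primary_layouts,
                         secondary_layouts = NULL, out_dir = NULL,
                         config = pipeline_config(), deficiencies = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$min_n < config$qc$min_n)
    stop("validation: min_n (", config$min_n,
         ") below the QC minimum usable size (", config$qc$min_n, ")")
  if (is.character(measurements))
    measurements <- read_measurements(measurements, col_map = config$col_map)
  stage_ctx <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
  }
  samples <- stage_ctx("assembly", assemble_samples(measurements))
  usable <- Filter(is_usable, samples)
  qc_reports <- stage_ctx("qc", lapply(usable, qc_sample, control = config$qc))
  kept <- Filter(function(q) !"unusable" %in% q$flags && q$n_final >= 2L,
                 qc_reports)
  fits <- stage_ctx("fa", lapply(kept, function(q) fa_fit(q$sample)))
  summaries <- group_summaries(fits)
  run <- function(layouts, stage) {
    ## samples are keyed by genotype within each layout's series, so the
    ## same genotype label may recur across stages/series without collision
    stage_ctx(stage, {
      parts <- lapply(layouts, function(lay) {
        ser <- Filter(function(s) s$series == lay$series_id, samples)
        flat <- stats::setNames(ser,
                                vapply(ser, function(s) s$genotype, ""))
        run_series(lay, flat, stage = stage, alpha = config$alpha,
                   qc = config$qc, min_n = config$min_n, mode = config$mode)
      })
      res <- do.call(rbind, lapply(parts, as.data.frame))
      rownames(res) <- NULL
      class(res) <- c("screen_result", "data.frame")
      res
    })
  }
  primary <- run(primary_layouts, "primary")
  secondary <- if (!is.null(secondary_layouts))
    run(secondary_layouts, "secondary")
  agg <- if (!is.null(secondary))
    aggregate_two_stage(primary, secondary, alpha = config$alpha)
  assoc <- stage_ctx("association", {
    rows <- list()
    sd_chk <- size_dependence(summaries$fa10a, summaries$mean_size)
    rows$fa_vs_size <- data.frame(
      analysis = "fa10a_vs_mean_size", transform = "identity",
      r = sd_chk$r, p = sd_chk$p, n = sd_chk$n,
      note = if (isTRUE(sd_chk$concern)) "allometry_concern" else "",
      stringsAsFactors = FALSE)
    civ <- correlate_groups(summaries$fa10a,
                            summaries$interindividual_variance,
                            transform = "log10")
    rows$fa_vs_iv <- data.frame(
      analysis = "log10_fa10a_vs_log10_interindividual_variance",
      transform = "log10", r = civ$r, p = civ$p, n = civ$n, note = "",
      stringsAsFactors = FALSE)
    if (!is.null(deficiencies) && !is.null(secondary)) {
      sec <- as.data.frame(secondary)
      m <- merge(sec[!is.na(sec$fold_change),
                     c("deficiency", "fold_change")],
                 deficiencies[c("name", "span")],
                 by.x = "deficiency", by.y = "name")
      fs <- correlate_groups(m$fold_change, m$span)
      rows$fold_vs_span <- data.frame(
        analysis = "fold_change_vs_deficiency_span", transform = "identity",
        r = fs$r, p = fs$p, n = fs$n, note = "", stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  })
  log <- list(
    package_version = as.character(utils::packageVersion("wingFA")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = list(alpha = config$alpha, qc = unclass(config$qc),
                  min_n = config$min_n, mode = config$mode,
                  seed = config$seed),
    n_measurements = nrow(measurements),
    n_samples = length(samples),
    excluded_individuals = attr(samples, "excluded"),
    removed_by_qc = lapply(qc_reports, function(q) q$removed_ids),
    qc_flags = lapply(qc_reports, function(q) q$flags))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_artifact(qc_report_table(qc_reports),
                       file.path(out_dir, "qc_report.tsv"), config)
    write_tsv_artifact(summaries, file.path(out_dir, "fa_results.tsv"),
                       config)
    write_tsv_artifact(as.data.frame(primary),
                       file.path(out_dir, "screen_primary.tsv"), config)
    if (!is.null(secondary)) {
      write_tsv_artifact(as.data.frame(secondary),
                         file.path(out_dir, "screen_secondary.tsv"), config)
      write_tsv_artifact(agg$confirmed,
                         file.path(out_dir, "confirmed_modifiers.tsv"),
                         config)
    }
    write_tsv_artifact(assoc, file.path(out_dir, "associations.tsv"),
                       config)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         dataframe = "rows")
  }
  invisible(list(samples = samples, qc = qc_reports, fits = fits,
                 summaries = summaries, primary = primary,
                 secondary = secondary, aggregate = agg,
                 associations = assoc, log = log))
}
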