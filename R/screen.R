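## Two-stage modifier screen: per-series F tests against internal controls,
## Holm correction within series, fold-change classification, and
## primary/secondary aggregation.
##
## Every experimental series carries its own positive control (the
## destabilized background alone) because absolute FA levels drift between
## experiments; all comparisons are within-series. The secondary stage
## additionally compares each deficiency-alone genotype with the series
## negative control (undestabilized background), to detect deficiencies
## that perturb FA on their own.

#' Series layout
#'
#' Describes one experimental series: which genotype label is the positive
#' control, which (for the secondary stage) is the negative control, and
#' the expected experimental genotype per deficiency. Deficiencies whose
#' expected genotype yields no sample are scored lethal, so the layout
#' lists *expected* genotypes, not just observed ones.
#'
#' @param series_id Series identifier.
#' @param experimental Named character vector: deficiency name ->
#'   experimental genotype label (deficiency combined with the destabilized
#'   background). At most 25 per series.
#' @param positive_control Genotype label of the series positive control.
#' @param negative_control Genotype label of the negative control
#'   (secondary stage), or `NA`.
#' @param df_alone Optional named character vector: deficiency name ->
#'   deficiency-alone genotype label (secondary stage).
#' @return A list of class `series_layout`.
#' @export
series_layout <- function(series_id, experimental, positive_control,
                          negative_control = NA_character_,
                          df_alone = NULL) {
  stopifnot(length(experimental) >= 1L, length(experimental) <= 25L,
            !is.null(names(experimental)), all(nzchar(names(experimental))))
  if (!is.null(df_alone))
    stopifnot(all(names(df_alone) %in% names(experimental)))
  structure(list(series_id = series_id, experimental = experimental,
                 positive_control = positive_control,
                 negative_control = negative_control,
                 df_alone = df_alone),
            class = "series_layout")
}

#' Holm step-down multiple-testing adjustment
#'
#' Adjusts one series' family of raw p-values by the Holm step-down
#' procedure (monotonicity enforced), controlling the family-wise error
#' rate within the series. Thin wrapper over
#' [stats::p.adjust()]`(method = "holm")` so the screen's adjustment is a
#' single auditable surface.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order; always `>=` raw.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "holm")
}

#' Classify one screen comparison
#'
#' Pure decision rule: a deficiency is `"decreasing"` (suppressor) when its
#' Holm-adjusted p-value is below `alpha` and its FA10a fold change is
#' below 1, `"enhancing"` when adjusted p < `alpha` and fold > 1, and
#' `"neutral"` otherwise. An undefined fold change (non-positive reference
#' FA10a) classifies as neutral with a flag.
#'
#' @param p_adjusted Holm-adjusted p-value.
#' @param fold_change FA10a fold change vs the series positive control.
#' @param alpha Significance level (default 0.05).
#' @return `"decreasing"`, `"enhancing"`, or `"neutral"`.
#' @examples
#' classify_comparison(0.0468, 0.37329)  # decreasing
#' classify_comparison(0.00434, 3.67005) # enhancing
#' classify_comparison(0.2, 2.0)         # neutral
#' @export
classify_comparison <- function(p_adjusted, fold_change, alpha = 0.05) {
  if (is.na(fold_change) || is.na(p_adjusted)) return("neutral")
  if (p_adjusted < alpha && fold_change < 1) return("decreasing")
  if (p_adjusted < alpha && fold_change > 1) return("enhancing")
  "neutral"
}

#' Run one series of the modifier screen
#'
#' For every deficiency of the layout: fit the FA model to the
#' (QC-filtered) experimental sample, compare it with the series positive
#' control by [compare_fa()], Holm-adjust the raw p-values within the
#' series, and classify by adjusted p and fold change. Deficiencies whose
#' expected genotype is absent or below `min_n` individuals are scored
#' `"lethal"`; samples the QC battery flags unusable are `"unmeasurable"`.
#' In the secondary stage, each deficiency-alone genotype is additionally
#' compared with the series negative control; these comparisons form their
#' own Holm family (they test a different null) and never affect the main
#' classification.
#'
#' @param layout A [series_layout()].
#' @param samples Named list of `genotype_sample` objects (names =
#'   genotype labels).
#' @param stage `"primary"` or `"secondary"`.
#' @param alpha Significance level on Holm-adjusted p-values (default 0.05).
#' @param qc A [qc_control()]; set `qc = NULL` to skip QC filtering.
#' @param min_n Minimum individuals for a viable genotype (default 10);
#'   below it the cross is scored lethal/sub-lethal.
#' @param mode Test mode passed to [compare_fa()].
#' @return A `data.frame` of class `screen_result`, one row per deficiency:
#'   series, stage, deficiency, n, fa10a, fa10a_control, f, p_raw, p_adj,
#'   fold_change, classification, qc_flags, and (secondary) the
#'   `alone_*` columns of the deficiency-alone vs negative-control family.
#'   The positive-control fit is attached as attribute `"control_fit"`.
#' @export
run_series <- function(layout, samples, stage = c("primary", "secondary"),
                       alpha = 0.05, qc = qc_control(), min_n = 10L,
                       mode = c("interaction", "fa10a")) {
  stage <- match.arg(stage)
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "series_layout"))
  pos <- samples[[layout$positive_control]]
  if (is.null(pos))
    stop("series ", layout$series_id, ": positive control '",
         layout$positive_control, "' has no sample")
  prep <- function(s) {       # QC-filter a sample; NULL if unusable
    if (!is.null(qc)) {
      rep_ <- qc_sample(s, qc)
      if ("unusable" %in% rep_$flags || rep_$n_final < 2L) return(list(fit = NULL, qc = rep_))
      list(fit = fa_fit(rep_$sample), qc = rep_)
    } else list(fit = fa_fit(s), qc = NULL)
  }
  posp <- prep(pos)
  if (is.null(posp$fit))
    stop("series ", layout$series_id, ": positive control failed QC")
  control_fit <- posp$fit
  defs <- names(layout$experimental)
  rows <- lapply(defs, function(def) {
    lab <- layout$experimental[[def]]
    out <- data.frame(series = layout$series_id, stage = stage,
                      deficiency = def, genotype = lab, n = NA_integer_,
                      fa10a = NA_real_, fa10a_control = control_fit$fa10a,
                      f = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                      p_raw = NA_real_, p_adj = NA_real_,
                      fold_change = NA_real_, fold_flag = FALSE,
                      classification = NA_character_, qc_flags = "",
                      stringsAsFactors = FALSE)
    s <- samples[[lab]]
    if (is.null(s) || s$n < min_n) {
      out$n <- if (is.null(s)) 0L else s$n
      out$classification <- "lethal"
      return(out)
    }
    pr <- prep(s)
    if (!is.null(pr$qc)) out$qc_flags <- paste(pr$qc$flags, collapse = ";")
    if (is.null(pr$fit)) {
      out$n <- pr$qc$n_final
      out$classification <- "unmeasurable"
      return(out)
    }
    cmp <- compare_fa(pr$fit, control_fit, mode = mode)
    out$n <- pr$fit$n
    out$fa10a <- pr$fit$fa10a
    out$f <- cmp$f; out$df1 <- cmp$df[1]; out$df2 <- cmp$df[2]
    out$p_raw <- cmp$p
    out$fold_change <- cmp$fold_change
    out$fold_flag <- cmp$fold_flag
    out
  })
  res <- do.call(rbind, rows)
  tested <- !is.na(res$p_raw)
  res$p_adj[tested] <- holm_adjust(res$p_raw[tested])
  res$classification[tested] <- mapply(classify_comparison,
                                       res$p_adj[tested],
                                       res$fold_change[tested],
                                       MoreArgs = list(alpha = alpha))
  if (stage == "secondary" && !is.null(layout$df_alone)) {
    res$alone_n <- NA_integer_; res$alone_fa10a <- NA_real_
    res$alone_f <- NA_real_; res$alone_p_raw <- NA_real_
    res$alone_p_adj <- NA_real_; res$alone_fold <- NA_real_
    neg <- samples[[layout$negative_control]]
    if (is.null(neg))
      stop("series ", layout$series_id,
           ": secondary stage needs the negative control '",
           layout$negative_control, "'")
    negp <- prep(neg)
    if (is.null(negp$fit))
      stop("series ", layout$series_id, ": negative control failed QC")
    for (def in names(layout$df_alone)) {
      s <- samples[[layout$df_alone[[def]]]]
      if (is.null(s) || s$n < min_n) next
      pr <- prep(s)
      if (is.null(pr$fit)) next
      cmp <- compare_fa(pr$fit, negp$fit, mode = mode)
      i <- match(def, res$deficiency)
      res$alone_n[i] <- pr$fit$n
      res$alone_fa10a[i] <- pr$fit$fa10a
      res$alone_f[i] <- cmp$f
      res$alone_p_raw[i] <- cmp$p
      res$alone_fold[i] <- cmp$fold_change
    }
    tested_a <- !is.na(res$alone_p_raw)
    res$alone_p_adj[tested_a] <- holm_adjust(res$alone_p_raw[tested_a])
    attr(res, "negative_control_fit") <- negp$fit
  }
  attr(res, "control_fit") <- control_fit
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Run several series and stack the rows
#'
#' @param layouts List of [series_layout()] objects.
#' @param samples Named list of `genotype_sample` objects covering all
#'   series.
#' @param ... Passed to [run_series()].
#' @return A stacked `screen_result` data frame.
#' @export
run_screen <- function(layouts, samples, ...) {
  parts <- lapply(layouts, run_series, samples = samples, ...)
  res <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(res) <- NULL
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Aggregate the two screen stages into confirmed modifiers
#'
#' A deficiency is a *confirmed modifier* when it is significant with the
#' same direction (decreasing or enhancing) in both the primary and the
#' secondary stage. Deficiencies significant in the primary stage only are
#' dropped; deficiencies tested in the secondary stage only are reported
#' as not confirmable. Separately, deficiencies whose deficiency-alone
#' genotype differs significantly from the negative control are listed as
#' intrinsic FA effects.
#'
#' @param primary,secondary `screen_result` data frames from the two stages.
#' @param alpha Significance level for the deficiency-alone family
#'   (default 0.05).
#' @return A list: `confirmed` (deficiency, classification, per-stage fold
#'   changes and adjusted p), `df_alone_effects` (secondary rows whose
#'   deficiency-alone comparison is significant, with direction), and
#'   `unconfirmable` (in secondary only).
#' @export
aggregate_two_stage <- function(primary, secondary, alpha = 0.05) {
  p <- as.data.frame(primary)[c("deficiency", "classification",
                                "fold_change", "p_adj")]
  s <- as.data.frame(secondary)[c("deficiency", "classification",
                                  "fold_change", "p_adj")]
  names(p)[2:4] <- paste0(names(p)[2:4], "_primary")
  names(s)[2:4] <- paste0(names(s)[2:4], "_secondary")
  m <- merge(p, s, by = "deficiency")
  conf <- m[!is.na(m$classification_primary) &
            m$classification_primary %in% c("decreasing", "enhancing") &
            m$classification_primary == m$classification_secondary, ,
            drop = FALSE]
  conf$classification <- conf$classification_primary
  conf <- conf[order(conf$deficiency), c("deficiency", "classification",
                                         "fold_change_primary",
                                         "p_adj_primary",
                                         "fold_change_secondary",
                                         "p_adj_secondary")]
  rownames(conf) <- NULL
  unconf <- setdiff(s$deficiency, p$deficiency)
  alone <- as.data.frame(secondary)
  if ("alone_p_adj" %in% names(alone)) {
    alone <- alone[!is.na(alone$alone_p_adj) & alone$alone_p_adj < alpha,
                   c("deficiency", "series", "alone_fold", "alone_p_adj"),
                   drop = FALSE]
    alone$direction <- ifelse(is.na(alone$alone_fold), NA_character_,
                              ifelse(alone$alone_fold > 1, "increase",
                                     "decrease"))
    rownames(alone) <- NULL
  } else {
    alone <- data.frame(deficiency = character(), series = character(),
                        alone_fold = numeric(), alone_p_adj = numeric(),
                        direction = character(), stringsAsFactors = FALSE)
  }
  list(confirmed = conf, df_alone_effects = alone, unconfirmable = unconf)
}
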