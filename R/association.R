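## Cross-genotype association analyses: inter-individual variance (a
## canalization proxy) and Pearson correlations between group summaries
## (FA fold change vs deficiency span, FA vs mean size, log FA vs log
## inter-individual variance).

#' Inter-individual variance of the trait
#'
#' The sample variance (denominator n - 1) of the per-individual mean trait
#' value (each individual averaged over both sides and all replicates)
#' within one genotype sample. Because it pools genetic and
#' micro-environmental differences among individuals, it serves as an
#' inverse proxy for canalization.
#'
#' @param sample A `genotype_sample` with n >= 2.
#' @return Non-negative scalar in squared trait units; `NA` with a warning
#'   for n < 2.
#' @examples
#' interindividual_variance(simulate_sample(seed = 3))
#' @export
interindividual_variance <- function(sample) {
  sample <- as_genotype_sample(sample)
  if (sample$n < 2L) {
    warning("inter-individual variance undefined for n < 2")
    return(NA_real_)
  }
  stats::var(rowMeans(sample$y, dims = 1L))
}

#' Pearson correlation between two group-level summaries
#'
#' Correlates paired group summaries across genotypes, optionally on the
#' log10 scale for quantities spanning orders of magnitude (e.g. FA10a vs
#' inter-individual variance). Non-positive values under the log transform
#' are excluded and reported. The correlation coefficient is the quantity
#' of interest; the two-sided t-based p-value is emitted as a descriptive
#' companion only.
#'
#' @param x,y Numeric vectors of equal length (one entry per genotype).
#' @param transform `"identity"` or `"log10"` (applied to both variables).
#' @return A list: `r`, `p`, `n` (pairs used), `excluded` (indices dropped
#'   as NA or non-positive under log10), `transform`, `flags`
#'   (`"degenerate"` when either variable has zero variance).
#' @examples
#' correlate_groups(1:10, (1:10)^2, transform = "log10")  # r = 1
#' @export
correlate_groups <- function(x, y, transform = c("identity", "log10")) {
  transform <- match.arg(transform)
  stopifnot(length(x) == length(y))
  drop <- !stats::complete.cases(x, y)
  if (transform == "log10") drop <- drop | x <= 0 | y <= 0
  excluded <- which(drop)
  x <- x[!drop]; y <- y[!drop]
  if (transform == "log10") { x <- log10(x); y <- log10(y) }
  if (length(x) < 3L)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                excluded = excluded, transform = transform,
                flags = "too_few_pairs"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                excluded = excluded, transform = transform,
                flags = "degenerate"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       excluded = excluded, transform = transform, flags = character())
}

#' Summarize fitted genotypes for association analyses
#'
#' Collects per-genotype summaries (FA10a, mean size, inter-individual
#' variance) from a list of [fa_fit()] objects into one data frame, the
#' input for [correlate_groups()] and [size_dependence()].
#'
#' @param fits A list of `fa_fit` objects.
#' @return A `data.frame` with columns `genotype`, `series`, `n`, `r`,
#'   `fa10a`, `me_variance`, `negative_flag`, `mean_size`,
#'   `interindividual_variance`.
#' @export
group_summaries <- function(fits) {
  stopifnot(length(fits) > 0L, all(vapply(fits, inherits, TRUE, "fa_fit")))
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(genotype = f$genotype, series = f$series, n = f$n, r = f$r,
               fa10a = f$fa10a, me_variance = f$me_variance,
               negative_flag = f$negative_flag, mean_size = f$mean_size,
               interindividual_variance = f$interindividual_variance,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
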