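## Sample-quality battery on signed asymmetry.
##
## FA inference assumes the per-individual signed left-right difference is
## approximately normal: bimodality suggests antisymmetry, heavy skew or
## single wild values suggest gross measurement errors. Each sample is
## therefore screened with Shapiro-Wilk and Lilliefors tests plus
## bias-adjusted skewness/kurtosis bounds, and rare failing individuals are
## eliminated (never imputed) under a deterministic, capped rule.

#' Per-individual signed asymmetry
#'
#' For each individual, the mean over replicates of the right side minus
#' the mean over replicates of the left side, in trait units. This is the
#' vector the QC normality battery operates on.
#'
#' @param sample A `genotype_sample`.
#' @return A named numeric vector (names = individual ids, stable order).
#' @examples
#' signed_asymmetry(simulate_sample(n = 5, seed = 1))
#' @export
signed_asymmetry <- function(sample) {
  sample <- as_genotype_sample(sample)
  cell <- rowMeans(sample$y, dims = 2L)  # n x 2 (L, R)
  stats::setNames(cell[, "R"] - cell[, "L"], sample$individuals)
}

#' Bias-adjusted sample skewness and excess kurtosis
#'
#' Small-sample-corrected moment statistics of a numeric vector, the
#' estimators usually denoted G1 and G2:
#' \preformatted{G1 = b1 * sqrt(n (n - 1)) / (n - 2)
#' G2 = ((n + 1) (b2 - 3) + 6) (n - 1) / ((n - 2) (n - 3))}
#' where `b1 = m3 / m2^1.5`, `b2 = m4 / m2^2` and `m_k` is the k-th central
#' sample moment. G2 is excess kurtosis: 0 for a normal distribution, so the
#' conventional acceptance window is `[-3, 3]` (raw kurtosis below -3 is
#' impossible, hence the bounds are read on the excess scale).
#'
#' @param d Numeric vector, length >= 4.
#' @return A list with `g1` and `g2`.
#' @export
asymmetry_moments <- function(d) {
  n <- length(d)
  if (n < 4L) stop("need at least 4 values for moment statistics")
  m <- d - mean(d)
  m2 <- mean(m^2)
  if (m2 == 0) return(list(g1 = NaN, g2 = NaN))
  b1 <- mean(m^3) / m2^1.5
  b2 <- mean(m^4) / m2^2
  g1 <- b1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * (b2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  list(g1 = g1, g2 = g2)
}

#' Normality tests of signed asymmetry
#'
#' Shapiro-Wilk and Lilliefors (Kolmogorov-Smirnov with estimated mean and
#' SD; p-values by the Dallal-Wilkinson approximation, as implemented in
#' \pkg{nortest}) on a vector of signed asymmetries.
#'
#' @param d Numeric vector.
#' @return A list: `shapiro_p`, `lilliefors_p`, `flags` (character vector;
#'   `"too_small"` when n < 5, `"degenerate"` for a constant vector, in
#'   which cases the p-values are `NA`).
#' @export
qc_normality <- function(d) {
  flags <- character()
  if (length(d) < 5L) {
    return(list(shapiro_p = NA_real_, lilliefors_p = NA_real_,
                flags = "too_small"))
  }
  if (stats::sd(d) == 0) {
    return(list(shapiro_p = NA_real_, lilliefors_p = NA_real_,
                flags = "degenerate"))
  }
  list(shapiro_p = stats::shapiro.test(d)$p.value,
       lilliefors_p = nortest::lillie.test(d)$p.value,
       flags = flags)
}

#' QC thresholds
#'
#' @param alpha_norm Significance level for both normality tests (default
#'   0.05).
#' @param g1_bound Acceptance bound on |skewness G1| (default 0.5).
#' @param g2_bound Acceptance bound on |excess kurtosis G2| (default 3).
#' @param max_removals Cap on outlier eliminations per sample (default 3).
#' @param min_n Minimum usable sample size after removals (default 10).
#' @return A list of class `qc_control`.
#' @export
qc_control <- function(alpha_norm = 0.05, g1_bound = 0.5, g2_bound = 3,
                       max_removals = 3L, min_n = 10L) {
  stopifnot(alpha_norm > 0, alpha_norm < 1, g1_bound > 0, g2_bound > 0,
            max_removals >= 0, min_n >= 4)
  structure(list(alpha_norm = alpha_norm, g1_bound = g1_bound,
                 g2_bound = g2_bound, max_removals = as.integer(max_removals),
                 min_n = as.integer(min_n)),
            class = "qc_control")
}

qc_evaluate <- function(d, control) {
  norm <- qc_normality(d)
  mom <- if (length(d) >= 4L) asymmetry_moments(d) else list(g1 = NA_real_,
                                                            g2 = NA_real_)
  testable <- length(norm$flags) == 0L
  pass <- testable &&
    norm$shapiro_p > control$alpha_norm &&
    norm$lilliefors_p > control$alpha_norm &&
    abs(mom$g1) <= control$g1_bound &&
    mom$g2 >= -control$g2_bound && mom$g2 <= control$g2_bound
  list(shapiro_p = norm$shapiro_p, lilliefors_p = norm$lilliefors_p,
       g1 = mom$g1, g2 = mom$g2, pass = isTRUE(pass), flags = norm$flags)
}

## Drop individuals from a balanced sample, keeping it balanced.
subset_sample <- function(sample, keep) {
  d <- sample$data[sample$data$individual %in% keep, , drop = FALSE]
  new_genotype_sample(d, genotype = sample$genotype, series = sample$series,
                      r = sample$r)
}

#' Quality-control a genotype sample
#'
#' Runs the full battery on the signed asymmetries and, while the sample
#' fails any threshold and the removal cap is not reached, eliminates the
#' individual with the largest robust z score `|d_i - median(d)| / MAD`
#' (falling back to the absolute deviation from the median when the MAD is
#' zero), re-testing after each removal. The procedure is deterministic;
#' a sample that still fails at the cap is flagged `"cap_reached"`, never
#' silently passed, and a sample that would shrink below `min_n` is flagged
#' `"unusable"`. Measurement values are never altered, only membership.
#'
#' @param sample A `genotype_sample`.
#' @param control A [qc_control()] list.
#' @return An object of class `qc_report`: `genotype`, `series`,
#'   `n_initial`, `n_final`, `removed_ids`, `shapiro_p`, `lilliefors_p`,
#'   `g1`, `g2`, `pass`, `flags`, `d` (final signed asymmetries), and
#'   `sample` (the filtered `genotype_sample`).
#' @examples
#' qc_sample(simulate_sample(seed = 7))
#' @export
qc_sample <- function(sample, control = qc_control()) {
  sample <- as_genotype_sample(sample)
  n_initial <- sample$n
  removed <- character()
  flags <- character()
  repeat {
    d <- signed_asymmetry(sample)
    ev <- qc_evaluate(d, control)
    flags <- union(flags, ev$flags)
    if (ev$pass || length(ev$flags) > 0L) break
    if (length(removed) >= control$max_removals) {
      flags <- union(flags, "cap_reached")
      break
    }
    if (sample$n - 1L < control$min_n) {
      flags <- union(flags, "unusable")
      break
    }
    dev <- abs(d - stats::median(d))
    scale <- stats::mad(d)
    z <- if (scale > 0) dev / scale else dev
    worst <- names(which.max(z))
    removed <- c(removed, worst)
    sample <- subset_sample(sample, setdiff(sample$individuals, worst))
  }
  structure(list(genotype = sample$genotype, series = sample$series,
                 n_initial = n_initial, n_final = sample$n,
                 removed_ids = removed,
                 shapiro_p = ev$shapiro_p, lilliefors_p = ev$lilliefors_p,
                 g1 = ev$g1, g2 = ev$g2, pass = ev$pass, flags = flags,
                 d = d, sample = sample, control = control),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, digits = 4, ...) {
  cat("QC report: ", x$genotype, " (series ", x$series, ")\n", sep = "")
  cat("  n ", x$n_initial, " -> ", x$n_final, sep = "")
  if (length(x$removed_ids))
    cat("  (removed: ", paste(x$removed_ids, collapse = ", "), ")", sep = "")
  cat("\n  Shapiro-Wilk p = ", format(x$shapiro_p, digits = digits),
      ", Lilliefors p = ", format(x$lilliefors_p, digits = digits),
      "\n  G1 = ", format(x$g1, digits = digits),
      ", G2 = ", format(x$g2, digits = digits), "\n", sep = "")
  cat("  ", if (x$pass) "PASS" else "FAIL", sep = "")
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Size-dependence (allometry) check across genotypes
#'
#' When mean size differs among genotypes, apparent FA differences can be
#' positive allometry in disguise — larger genotypes presenting larger
#' asymmetries. This check correlates FA10a with group mean size across
#' genotypes: a positive correlation is an allometry concern, a negative or
#' null one is not (FA differences then reflect genuine developmental
#' instability differences).
#'
#' @param fa Numeric vector of FA10a estimates, one per genotype.
#' @param size Numeric vector of group mean sizes, same length.
#' @return A list: `r`, `p`, `n`, `slope_sign` (`"+"`, `"-"`, `"0"`),
#'   `concern` (logical), `flags`.
#' @export
size_dependence <- function(fa, size) {
  stopifnot(length(fa) == length(size))
  keep <- stats::complete.cases(fa, size)
  fa <- fa[keep]; size <- size[keep]
  if (length(fa) < 3L)
    return(list(r = NA_real_, p = NA_real_, n = length(fa),
                slope_sign = NA_character_, concern = NA,
                flags = "too_few_groups"))
  if (stats::sd(fa) == 0 || stats::sd(size) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(fa),
                slope_sign = NA_character_, concern = NA,
                flags = "degenerate"))
  ct <- stats::cor.test(size, fa, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, n = length(fa),
       slope_sign = if (r > 0) "+" else if (r < 0) "-" else "0",
       concern = r > 0 && ct$p.value < 0.05, flags = character())
}
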