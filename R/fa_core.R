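## Core estimator: balanced two-way mixed-model ANOVA of repeated bilateral
## measurements and the measurement-error-corrected FA10a index.
##
## Model for measurement m_{isr} of individual i, side s, replicate r:
##   m_{isr} = mu + I_i + D_s + A_{is} + e_{isr}
## with individual I random, side D fixed (directional asymmetry), the
## individual x side interaction A the true fluctuating asymmetry
## (Var A = sigma_FA^2), and replicate error e the measurement error
## (Var e = sigma_ME^2). Because measurement error behaves like genuine FA
## (non-directional random variation), the interaction mean square alone
## overestimates FA; FA10a removes the error component:
##   FA10a = (MS_interaction - MS_residual) / r,
## an estimate of sigma_FA^2 in squared trait units.

#' Two-way mixed-model ANOVA of a balanced bilateral block
#'
#' Decomposes a balanced block (`n` individuals x 2 sides x `r` replicates)
#' into the four mean squares of the two-way model with replication:
#' side, individual, individual-by-side interaction, and residual
#' (replicate) strata, computed from the marginal and cell means of the
#' balanced design. Mean squares are identical whether individual is
#' treated as fixed or random; the mixed-model structure matters only for
#' which F ratios are meaningful (see [directional_asymmetry()],
#' [compare_fa()]).
#'
#' @param sample A `genotype_sample` (see [assemble_samples()]), or a
#'   measurement `data.frame` containing exactly one genotype/series group.
#' @return An object of class `fa_anova`: a list with `ms` and `df` (named
#'   vectors over `side`, `individual`, `interaction`, `residual`), `ss`,
#'   `n`, `r`, `grand_mean`, and `side_means`.
#' @examples
#' s <- simulate_sample(n = 10, seed = 1)
#' fa_anova(s)
#' @export
fa_anova <- function(sample) {
  sample <- as_genotype_sample(sample)
  if (sample$n < 2L)
    stop("ANOVA needs at least 2 individuals (got ", sample$n, ")")
  if (sample$r < 2L)
    stop("measurement error not separable: need r >= 2 replicates per side")
  y <- sample$y
  n <- sample$n; r <- sample$r; s <- 2L
  grand <- mean(y)
  ind_means  <- rowMeans(y, dims = 1L)                      # length n
  side_means <- apply(y, 2L, mean)                          # length 2
  cell_means <- rowMeans(y, dims = 2L)                      # n x 2
  ss_side <- n * r * sum((side_means - grand)^2)
  ss_ind  <- s * r * sum((ind_means - grand)^2)
  inter   <- sweep(sweep(cell_means, 1L, ind_means), 2L, side_means) + grand
  ss_int  <- r * sum(inter^2)
  ss_res  <- sum((y - as.vector(cell_means))^2)
  df <- c(side = s - 1L, individual = n - 1L,
          interaction = (n - 1L) * (s - 1L), residual = n * s * (r - 1L))
  ss <- c(side = ss_side, individual = ss_ind,
          interaction = ss_int, residual = ss_res)
  structure(list(ms = ss / df, ss = ss, df = df, n = n, r = r,
                 grand_mean = grand, side_means = side_means),
            class = "fa_anova")
}

as_genotype_sample <- function(x) {
  if (inherits(x, "genotype_sample")) return(x)
  if (is.data.frame(x)) {
    samples <- assemble_samples(x)
    if (length(samples) != 1L)
      stop("expected a single genotype/series group, got ", length(samples))
    return(samples[[1L]])
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a genotype sample")
}

#' @export
print.fa_anova <- function(x, ...) {
  tab <- data.frame(Df = x$df, `Sum Sq` = x$ss, `Mean Sq` = x$ms,
                    check.names = FALSE)
  cat("Two-way mixed-model ANOVA (n = ", x$n, ", sides = 2, r = ", x$r,
      ")\n", sep = "")
  print(tab, ...)
  invisible(x)
}

#' Fit the fluctuating-asymmetry model to one genotype sample
#'
#' The central fitting function: runs [fa_anova()] on a balanced block of
#' repeated left/right measurements and derives
#' \itemize{
#'   \item `fa10a` — the measurement-error-corrected FA variance,
#'     `(MS_interaction - MS_residual) / r`, in squared trait units. A
#'     negative raw estimate (interaction MS below residual MS) is returned
#'     as-is with `negative_flag = TRUE`, never clamped;
#'   \item `me_variance` — the residual mean square, the per-measurement
#'     error variance;
#'   \item directional asymmetry — the signed mean right-minus-left
#'     difference with its F test (side MS over interaction MS);
#'   \item `mean_size` and `interindividual_variance` — group mean and the
#'     variance of the per-individual mean trait (a canalization proxy).
#' }
#'
#' @param object A `genotype_sample`, or a measurement `data.frame` holding
#'   one genotype/series group.
#' @param ... Unused.
#' @return An object of class `fa_fit` with components `genotype`, `series`,
#'   `n`, `r`, `anova` (the `fa_anova`), `fa10a`, `me_variance`,
#'   `negative_flag`, `da` (list `delta`, `f`, `p`), `mean_size`,
#'   `interindividual_variance`, and `signed_asymmetry` (per-individual
#'   right-minus-left means). Methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `simulate`, `plot`.
#' @examples
#' fit <- fa_fit(simulate_sample(seed = 42))
#' fit
#' coef(fit)
#' @export
fa_fit <- function(object, ...) UseMethod("fa_fit")

#' @rdname fa_fit
#' @export
fa_fit.genotype_sample <- function(object, ...) {
  tbl <- fa_anova(object)
  d <- signed_asymmetry(object)
  fit <- list(genotype = object$genotype, series = object$series,
              n = object$n, r = object$r, anova = tbl,
              fa10a = unname((tbl$ms["interaction"] - tbl$ms["residual"]) / object$r),
              me_variance = unname(tbl$ms["residual"]),
              negative_flag = unname(tbl$ms["interaction"] < tbl$ms["residual"]),
              da = directional_asymmetry(tbl),
              mean_size = tbl$grand_mean,
              interindividual_variance = interindividual_variance(object),
              signed_asymmetry = d,
              sample = object)
  class(fit) <- "fa_fit"
  fit
}

#' @rdname fa_fit
#' @export
fa_fit.data.frame <- function(object, ...) {
  fa_fit(as_genotype_sample(object), ...)
}

#' Extract the FA10a index
#'
#' @param x An `fa_fit` or `fa_anova` object.
#' @return The FA10a estimate (numeric scalar, squared trait units); may be
#'   negative when the interaction mean square falls below the residual mean
#'   square (pure measurement error).
#' @export
fa10a <- function(x) {
  if (inherits(x, "fa_fit")) return(x$fa10a)
  if (inherits(x, "fa_anova"))
    return(unname((x$ms["interaction"] - x$ms["residual"]) / x$r))
  stop("fa10a needs an fa_fit or fa_anova object")
}

#' Directional asymmetry: the fixed side effect
#'
#' Reports the signed mean right-minus-left difference and its F test. In
#' the mixed model the side mean square is tested over the individual-by-
#' side interaction (the random stratum in which the fixed side contrast
#' lives), with (1, n - 1) degrees of freedom.
#'
#' @param tbl An `fa_anova` (or `fa_fit`).
#' @return A list: `delta` (mean R - L, trait units), `f`, `df`, `p`.
#' @export
directional_asymmetry <- function(tbl) {
  if (inherits(tbl, "fa_fit")) tbl <- tbl$anova
  if (!inherits(tbl, "fa_anova")) stop("need an fa_anova object")
  if (tbl$df["interaction"] < 1L) stop("no interaction degrees of freedom")
  f <- unname(tbl$ms["side"] / tbl$ms["interaction"])
  list(delta = unname(tbl$side_means["R"] - tbl$side_means["L"]),
       f = f,
       df = c(1L, unname(tbl$df["interaction"])),
       p = stats::pf(f, 1, tbl$df[["interaction"]], lower.tail = FALSE))
}

#' Compare fluctuating asymmetry between two samples
#'
#' Tests for a difference in FA between two genotypes with an F test and
#' reports the FA10a fold change. Two modes:
#' \describe{
#'   \item{`"interaction"` (default)}{F is the ratio of the individual-by-
#'     side interaction mean squares, with `(n_a - 1, n_b - 1)` degrees of
#'     freedom. Under equal true FA *and* equal measurement error this
#'     statistic is exactly F distributed, which makes it the defensible
#'     standard test when the two samples share a measurement protocol.}
#'   \item{`"fa10a"`}{F is the ratio of the FA10a estimates themselves with
#'     the same nominal degrees of freedom. A difference of mean squares is
#'     not exactly F distributed, so this mode is approximate; it is
#'     provided for sensitivity analysis and is unavailable when either
#'     estimate is non-positive.}
#' }
#' The p-value is two-sided (twice the smaller tail, capped at 1), since a
#' modifier screen seeks both enhancers and suppressors. The fold change is
#' always the FA10a ratio `fa10a(a) / fa10a(b)`; when the denominator is
#' non-positive it is `NA` with `fold_flag` set, and the comparison is still
#' reported on the mean-square ratio.
#'
#' @param a,b `fa_fit` objects (or samples/data frames, which are fitted).
#' @param mode `"interaction"` or `"fa10a"`.
#' @return An object of class `fa_comparison`: `f`, `df`, `p`,
#'   `fold_change`, `ms_ratio`, `direction` (`"increase"`/`"decrease"`),
#'   `fold_flag`, `mode`, plus the two labels.
#' @examples
#' a <- fa_fit(simulate_sample(sigma_fa = 6, seed = 1, genotype = "mut"))
#' b <- fa_fit(simulate_sample(sigma_fa = 3, seed = 2, genotype = "ctl"))
#' compare_fa(a, b)
#' @export
compare_fa <- function(a, b, mode = c("interaction", "fa10a")) {
  mode <- match.arg(mode)
  if (!inherits(a, "fa_fit")) a <- fa_fit(a)
  if (!inherits(b, "fa_fit")) b <- fa_fit(b)
  df1 <- unname(a$anova$df["interaction"])
  df2 <- unname(b$anova$df["interaction"])
  ms_ratio <- unname(a$anova$ms["interaction"] / b$anova$ms["interaction"])
  fold_flag <- b$fa10a <= 0
  fold <- if (fold_flag) NA_real_ else a$fa10a / b$fa10a
  f <- switch(mode,
    interaction = ms_ratio,
    fa10a = {
      if (fold_flag || a$fa10a <= 0)
        stop("fa10a-ratio mode needs both estimates positive")
      fold
    })
  p <- two_sided_f_p(f, df1, df2)
  structure(list(label_a = a$genotype, label_b = b$genotype,
                 f = f, df = c(df1, df2), p = p,
                 fold_change = fold, ms_ratio = ms_ratio,
                 direction = if (isTRUE(fold > 1) ||
                                 (is.na(fold) && ms_ratio > 1)) "increase"
                             else "decrease",
                 fold_flag = fold_flag, mode = mode),
            class = "fa_comparison")
}

## Two-sided p for an F statistic: double the smaller tail, cap at 1.
two_sided_f_p <- function(f, df1, df2) {
  lo <- stats::pf(f, df1, df2)
  hi <- stats::pf(f, df1, df2, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

#' @export
print.fa_comparison <- function(x, digits = 4, ...) {
  cat("FA comparison (", x$mode, " mode): ", x$label_a, " vs ", x$label_b,
      "\n", sep = "")
  cat("  F = ", format(x$f, digits = digits), " on (", x$df[1], ", ",
      x$df[2], ") df,  two-sided p = ", format(x$p, digits = digits),
      "\n", sep = "")
  if (x$fold_flag) {
    cat("  FA10a fold change undefined (non-positive reference estimate);",
        "MS ratio =", format(x$ms_ratio, digits = digits), "\n")
  } else {
    cat("  FA10a fold change = ", format(x$fold_change, digits = digits),
        " (", x$direction, ")\n", sep = "")
  }
  invisible(x)
}

## ---- fa_fit methods ------------------------------------------------------

#' @export
print.fa_fit <- function(x, digits = 4, ...) {
  cat("FA fit: ", x$genotype, " (series ", x$series, "), n = ", x$n,
      ", r = ", x$r, "\n", sep = "")
  cat("  FA10a        = ", format(x$fa10a, digits = digits),
      if (x$negative_flag) "  [negative raw estimate]", "\n", sep = "")
  cat("  ME variance  = ", format(x$me_variance, digits = digits), "\n",
      sep = "")
  cat("  DA (R - L)   = ", format(x$da$delta, digits = digits),
      "  (F = ", format(x$da$f, digits = digits), ", p = ",
      format(x$da$p, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.fa_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.fa_fit")
}

#' @export
print.summary.fa_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("  mean size    = ", format(f$mean_size, digits = digits), "\n", sep = "")
  cat("  inter-individual variance = ",
      format(f$interindividual_variance, digits = digits), "\n", sep = "")
  cat("\n")
  print(f$anova, digits = digits)
  invisible(x)
}

#' @export
coef.fa_fit <- function(object, ...) {
  c(fa10a = object$fa10a,
    me_variance = object$me_variance,
    da_delta = object$da$delta,
    mean_size = object$mean_size,
    interindividual_variance = object$interindividual_variance)
}

#' @export
fitted.fa_fit <- function(object, ...) {
  cell <- rowMeans(object$sample$y, dims = 2L)
  d <- object$sample$data
  d$fitted <- cell[cbind(match(d$individual, rownames(cell)), match(d$side, c("L", "R")))]
  d$fitted
}

#' @export
residuals.fa_fit <- function(object, ...) {
  object$sample$data$length - fitted(object)
}

#' Simulate new samples from a fitted FA model
#'
#' Draws replicate datasets from the variance components implied by the
#' fitted mean squares: `sigma_FA^2` from FA10a (clamped at 0 if negative),
#' `sigma_ME^2` from the residual mean square, the inter-individual variance
#' from `(MS_individual - MS_interaction) / (2 r)` (clamped at 0), the fixed
#' side offset from the observed R - L difference, and the grand mean.
#'
#' @param object An `fa_fit`.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `genotype_sample` objects of the same dimensions.
#' @export
simulate.fa_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tbl <- object$anova
  sigma_ind2 <- max(0, unname(tbl$ms["individual"] - tbl$ms["interaction"]) /
                      (2 * object$r))
  lapply(seq_len(nsim), function(i)
    simulate_sample(mu_size = object$mean_size,
                    sigma_ind = sqrt(sigma_ind2),
                    delta_da = object$da$delta,
                    sigma_fa = sqrt(max(0, object$fa10a)),
                    sigma_me = sqrt(object$me_variance),
                    n = object$n, r = object$r,
                    genotype = object$genotype, series = object$series))
}

#' Diagnostic plot of a fitted FA model
#'
#' Normal Q-Q plot of the per-individual signed asymmetries (left panel) —
#' the distribution whose normality the QC battery tests — and replicate
#' differences against individual means (right panel), a visual check of
#' measurement error.
#'
#' @param x An `fa_fit`.
#' @param ... Passed to [stats::qqnorm()].
#' @return `x`, invisibly.
#' @export
plot.fa_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  stats::qqnorm(x$signed_asymmetry,
                main = paste0("Signed asymmetry: ", x$genotype), ...)
  stats::qqline(x$signed_asymmetry)
  y <- x$sample$y
  ind_mean <- rowMeans(y, dims = 1L)
  rep_range <- apply(y, c(1L, 2L), function(z) diff(range(z)))
  plot(rep(ind_mean, 2L), as.vector(rep_range),
       xlab = "individual mean size", ylab = "replicate range",
       main = "Measurement error")
  invisible(x)
}
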