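## Synthetic-data generator with the exact variance-component structure the
## two-way mixed ANOVA assumes:
##   m_{isr} = mu + I_i + D_s + A_{is} + e_{isr},
##   I ~ N(0, sigma_ind^2), D_L = -delta_da/2, D_R = +delta_da/2,
##   A ~ N(0, sigma_fa^2) independent per (individual, side),
##   e ~ N(0, sigma_me^2) per replicate.
## Under this model E[MS_res] = sigma_me^2, E[MS_int] = sigma_me^2 +
## r sigma_fa^2 (so E[FA10a] = sigma_fa^2), E[MS_side] = sigma_me^2 +
## r sigma_fa^2 + n r delta_da^2 / 2, and E[MS_ind] = sigma_me^2 +
## r sigma_fa^2 + 2 r sigma_ind^2.
##
## Default magnitudes emulate a Drosophila wing-length trait measured in
## micrometres: mean length 2500, inter-individual SD 50 (2% CV), a small
## directional asymmetry of 2, wild-type-like developmental noise
## sigma_fa = 3, and landmark digitization error sigma_me = 2 (repeatability
## far above 99%). Thirty individuals measured twice per side mirror the
## usual screen design.

#' Simulation configuration
#'
#' @param mu_size Mean trait size (default 2500, a wing length in um).
#' @param sigma_ind Inter-individual SD (default 50).
#' @param delta_da Fixed right-minus-left offset, directional asymmetry
#'   (default 2).
#' @param sigma_fa SD of the individual-by-side effect — true FA; FA10a
#'   estimates `sigma_fa^2` (default 3).
#' @param sigma_me Replicate measurement-error SD (default 2).
#' @param n Individuals per sample (default 30).
#' @param r Replicate measurements per side (default 2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mu_size = 2500, sigma_ind = 50, delta_da = 2,
                       sigma_fa = 3, sigma_me = 2, n = 30L, r = 2L) {
  stopifnot(sigma_ind >= 0, sigma_fa >= 0, sigma_me >= 0, n >= 2, r >= 2)
  structure(list(mu_size = mu_size, sigma_ind = sigma_ind,
                 delta_da = delta_da, sigma_fa = sigma_fa,
                 sigma_me = sigma_me, n = as.integer(n), r = as.integer(r)),
            class = "sim_config")
}

#' Simulate one balanced genotype sample
#'
#' Draws a complete balanced block from the generative model above. With a
#' `seed`, the result is bit-reproducible.
#'
#' @inheritParams sim_config
#' @param seed Optional integer seed (set via [set.seed()]).
#' @param genotype,series Labels attached to the sample; individual ids are
#'   prefixed with both, so samples from different genotypes can be pooled
#'   into one dataset without key collisions.
#' @param config Optional [sim_config()]; when given, its fields override
#'   the individual parameter defaults.
#' @return A `genotype_sample`. Values that would be non-positive are
#'   truncated at a small positive floor; if more than 0.1% of values are
#'   truncated, a warning reports the count.
#' @examples
#' s <- simulate_sample(n = 10, seed = 1)
#' fa_fit(s)
#' @export
simulate_sample <- function(mu_size = 2500, sigma_ind = 50, delta_da = 2,
                            sigma_fa = 3, sigma_me = 2, n = 30L, r = 2L,
                            seed = NULL, genotype = "sim", series = "S1",
                            config = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    mu_size <- config$mu_size; sigma_ind <- config$sigma_ind
    delta_da <- config$delta_da; sigma_fa <- config$sigma_fa
    sigma_me <- config$sigma_me; n <- config$n; r <- config$r
  }
  n <- as.integer(n); r <- as.integer(r)
  stopifnot(n >= 2L, r >= 2L)
  if (!is.null(seed)) set.seed(seed)
  ind  <- stats::rnorm(n, 0, sigma_ind)
  side_fx <- c(L = -delta_da / 2, R = delta_da / 2)
  a    <- matrix(stats::rnorm(n * 2L, 0, sigma_fa), n, 2L)
  eps  <- array(stats::rnorm(n * 2L * r, 0, sigma_me), dim = c(n, 2L, r))
  cell <- mu_size + ind + rep(side_fx, each = n) + a   # n x 2
  y    <- as.vector(cell) + eps                         # recycles over r
  floor_val <- max(1e-9, abs(mu_size) * 1e-6)
  n_trunc <- sum(y < floor_val)
  if (n_trunc > 0L) {
    y[y < floor_val] <- floor_val
    if (n_trunc > 0.001 * length(y))
      warning(n_trunc, " of ", length(y),
              " simulated values truncated at the positive floor")
  }
  ids <- sprintf("%s.%s.i%03d", series, genotype, seq_len(n))
  d <- data.frame(
    individual = rep(ids, each = 2L * r),
    genotype = genotype, series = series,
    side = rep(rep(c("L", "R"), each = r), times = n),
    replicate = rep(seq_len(r), times = 2L * n),
    length = as.vector(aperm(y, c(3L, 2L, 1L))),
    stringsAsFactors = FALSE)
  new_genotype_sample(d, genotype = genotype, series = series, r = r)
}

## Deterministic substream seed from a global seed and string labels, so
## adding a genotype to a scenario never perturbs the draws of the others.
## Polynomial rolling hash, kept below 2^31 - 1.
hash_seed <- function(seed, ...) {
  h <- 0
  for (tok in as.character(c(...))) {
    for (c in utf8ToInt(tok)) h <- (h * 31 + c) %% 2147483647
    h <- (h * 31 + 7) %% 2147483647
  }
  as.integer((h + (as.numeric(seed) %% 2147483647) * 1000003) %% 2147483647)
}

#' Screen scenario: a simulated multi-series modifier screen
#'
#' Describes a screen of `n_series` series of up to `per_series`
#' deficiencies each, all sharing a baseline configuration. The positive
#' control of every series is the destabilized background itself
#' (`baseline`); the negative control is the same background with its FA
#' component scaled down by `control_fa_ratio` (default 50, so the
#' positive/negative FA10a ratio is about 50, within the 30--70 range
#' typical of strongly destabilized systems). Each deficiency perturbs the
#' FA variance multiplicatively: its sample is drawn with
#' `sigma_fa^2 = fold x baseline sigma_fa^2`.
#'
#' @param n_series Number of series (default 2).
#' @param per_series Deficiencies per series (default 25, max 25).
#' @param planted Named numeric vector of true FA10a fold changes for
#'   selected deficiencies (names like `"Df003"`); all others are neutral
#'   (fold 1).
#' @param lethal Character vector of deficiency labels that are lethal when
#'   combined with the destabilized background (they yield no sample), or a
#'   single number in `[0, 1)`: the fraction of deficiencies to mark
#'   lethal (chosen deterministically from `seed`).
#' @param df_alone_fold Named numeric vector of fold changes applied to the
#'   negative-control-level FA of the deficiency-alone genotypes (secondary
#'   screen); default all 1 (no effect).
#' @param baseline A [sim_config()] for the positive control; the default
#'   uses `sigma_fa = sqrt(50) * 3`, i.e. a destabilized background with
#'   about 50-fold the wild-type FA variance.
#' @param control_fa_ratio Positive/negative control FA10a ratio (default 50).
#' @param seed Global integer seed; per-sample substreams are derived by
#'   stable hashing of (stage, series, genotype).
#' @return A list of class `screen_scenario` with a `truth` data frame
#'   (`deficiency`, `series`, `fold`, `df_alone_fold`, `lethal`, `class`).
#' @export
screen_scenario <- function(n_series = 2L, per_series = 25L,
                            planted = numeric(0), lethal = character(0),
                            df_alone_fold = numeric(0),
                            baseline = sim_config(sigma_fa = sqrt(50) * 3),
                            control_fa_ratio = 50, seed = 1L) {
  stopifnot(per_series >= 1L, per_series <= 25L, n_series >= 1L,
            control_fa_ratio > 0)
  n_def <- n_series * per_series
  defs <- sprintf("Df%03d", seq_len(n_def))
  series <- rep(sprintf("S%d", seq_len(n_series)), each = per_series)
  fold <- stats::setNames(rep(1, n_def), defs)
  if (length(planted)) {
    bad <- setdiff(names(planted), defs)
    if (length(bad)) stop("unknown planted deficiency: ",
                          paste(bad, collapse = ", "))
    fold[names(planted)] <- planted
  }
  if (is.numeric(lethal) && length(lethal) == 1L) {
    stopifnot(lethal >= 0, lethal < 1)
    k <- round(lethal * n_def)
    set.seed(hash_seed(seed, "lethal-draw"))
    lethal <- sample(setdiff(defs, names(planted)), k)
  }
  bad <- setdiff(lethal, defs)
  if (length(bad)) stop("unknown lethal deficiency: ",
                        paste(bad, collapse = ", "))
  dfold <- stats::setNames(rep(1, n_def), defs)
  if (length(df_alone_fold)) dfold[names(df_alone_fold)] <- df_alone_fold
  truth <- data.frame(
    deficiency = defs, series = series, fold = unname(fold),
    df_alone_fold = unname(dfold), lethal = defs %in% lethal,
    class = ifelse(defs %in% lethal, "lethal",
            ifelse(fold > 1, "enhancing",
            ifelse(fold < 1, "decreasing", "neutral"))),
    stringsAsFactors = FALSE)
  structure(list(n_series = as.integer(n_series),
                 per_series = as.integer(per_series),
                 baseline = baseline, control_fa_ratio = control_fa_ratio,
                 truth = truth, seed = as.integer(seed)),
            class = "screen_scenario")
}

## Draw one scenario sample with its substream seed.
scenario_sample <- function(scn, stage, series, genotype, sigma_fa) {
  cfg <- scn$baseline
  simulate_sample(mu_size = cfg$mu_size, sigma_ind = cfg$sigma_ind,
                  delta_da = cfg$delta_da, sigma_fa = sigma_fa,
                  sigma_me = cfg$sigma_me, n = cfg$n, r = cfg$r,
                  seed = hash_seed(scn$seed, stage, series, genotype),
                  genotype = genotype, series = series)
}

#' Simulate the primary stage of a modifier screen
#'
#' Generates, for every series of the scenario, the positive-control sample
#' and one sample per non-lethal deficiency combined with the destabilized
#' background (label `paste0(def, "+TG")`), plus the
#' series layouts. Lethal deficiencies emit no individuals and appear only
#' in the truth table.
#'
#' @param scn A [screen_scenario()].
#' @return A list: `samples` (named list of `genotype_sample`), `layouts`
#'   (list of [series_layout()]), `truth`, `scenario`.
#' @examples
#' scn <- screen_scenario(n_series = 1, per_series = 4,
#'                        planted = c(Df002 = 5), seed = 9)
#' sim <- simulate_screen(scn)
#' names(sim$samples)
#' @export
simulate_screen <- function(scn) {
  stopifnot(inherits(scn, "screen_scenario"))
  base_fa <- scn$baseline$sigma_fa
  samples <- list()
  layouts <- list()
  for (sid in unique(scn$truth$series)) {
    rows <- scn$truth[scn$truth$series == sid, ]
    pos_label <- paste0("CTRL+TG.", sid)
    samples[[pos_label]] <- scenario_sample(scn, "primary", sid, pos_label,
                                            base_fa)
    exper <- character(0)
    for (k in seq_len(nrow(rows))) {
      if (rows$lethal[k]) next
      lab <- paste0(rows$deficiency[k], "+TG")
      samples[[lab]] <- scenario_sample(scn, "primary", sid, lab,
                                        base_fa * sqrt(rows$fold[k]))
      exper <- c(exper, stats::setNames(lab, rows$deficiency[k]))
    }
    expected <- stats::setNames(paste0(rows$deficiency, "+TG"),
                                rows$deficiency)
    layouts[[sid]] <- series_layout(series_id = sid, experimental = expected,
                                    positive_control = pos_label)
  }
  list(samples = samples, layouts = layouts, truth = scn$truth,
       scenario = scn)
}

#' Simulate the secondary (replication) stage of a modifier screen
#'
#' Re-draws fresh data for a subset of deficiencies (the primary hits plus
#' any carried neutrals), adding for each a deficiency-alone genotype (FA at
#' the negative-control level times its `df_alone_fold`) and per-series
#' positive and negative controls. Substream seeds differ from the primary
#' stage, so the replication data are independent.
#'
#' @param scn A [screen_scenario()].
#' @param deficiencies Character vector of deficiency labels to retest.
#' @return Same shape as [simulate_screen()], with layouts carrying
#'   `negative_control` and the `df_alone` mapping.
#' @export
simulate_secondary <- function(scn, deficiencies) {
  stopifnot(inherits(scn, "screen_scenario"))
  bad <- setdiff(deficiencies, scn$truth$deficiency)
  if (length(bad)) stop("unknown deficiency: ", paste(bad, collapse = ", "))
  base_fa <- scn$baseline$sigma_fa
  neg_fa <- base_fa / sqrt(scn$control_fa_ratio)
  samples <- list()
  layouts <- list()
  truth <- scn$truth[scn$truth$deficiency %in% deficiencies, ]
  for (sid in unique(truth$series)) {
    rows <- truth[truth$series == sid, ]
    sec_id <- paste0(sid, "r")
    pos_label <- paste0("CTRL+TG.", sec_id)
    neg_label <- paste0("CTRL.", sec_id)
    samples[[pos_label]] <- scenario_sample(scn, "secondary", sec_id,
                                            pos_label, base_fa)
    samples[[neg_label]] <- scenario_sample(scn, "secondary", sec_id,
                                            neg_label, neg_fa)
    exper <- stats::setNames(paste0(rows$deficiency, "+TG"), rows$deficiency)
    alone <- stats::setNames(paste0(rows$deficiency, "alone"),
                             rows$deficiency)
    for (k in seq_len(nrow(rows))) {
      if (rows$lethal[k]) next
      samples[[exper[k]]] <- scenario_sample(scn, "secondary", sec_id,
                                             exper[[k]],
                                             base_fa * sqrt(rows$fold[k]))
      samples[[alone[k]]] <- scenario_sample(scn, "secondary", sec_id,
                                             alone[[k]],
                                             neg_fa * sqrt(rows$df_alone_fold[k]))
    }
    layouts[[sec_id]] <- series_layout(series_id = sec_id,
                                       experimental = exper,
                                       positive_control = pos_label,
                                       negative_control = neg_label,
                                       df_alone = alone)
  }
  list(samples = samples, layouts = layouts, truth = truth, scenario = scn)
}
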