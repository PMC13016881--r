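## Simulation scorecard: run a complete two-stage screen on generated data
## and score the confirmed-modifier list against the scenario's truth table.
## This is the package's power-exploration tool: with planted fold changes
## it measures sensitivity, with an all-neutral scenario it measures the
## realized family-wise error of the whole two-stage procedure.

#' Score a simulated two-stage screen against its truth table
#'
#' Simulates the primary stage of a [screen_scenario()], runs the screen,
#' carries the primary hits plus a few neutral deficiencies per series into
#' a simulated secondary stage (fresh data), aggregates the two stages, and
#' scores the confirmed modifiers against the scenario truth.
#'
#' The neutral carryover mirrors screen practice: a handful of
#' unremarkable deficiencies are re-tested alongside the hits to confirm
#' the absence of an effect (default 1 per series, roughly the published
#' screens' proportion of carried neutrals to hits).
#'
#' @param scn A [screen_scenario()].
#' @param carry_neutrals Neutral deficiencies re-tested per series
#'   (default 1); chosen deterministically from the scenario seed.
#' @param alpha,qc,min_n,mode Passed to [run_series()].
#' @return A list: `confirmed` (from [aggregate_two_stage()]), `truth`,
#'   `n_planted`, `correct_confirmed` (confirmed with the planted
#'   direction), `false_confirmed` (confirmed despite a neutral truth),
#'   `sensitivity`, and the per-stage `screen_result` tables.
#' @examples
#' scn <- screen_scenario(n_series = 1, per_series = 6,
#'                        planted = c(Df002 = 25),
#'                        baseline = sim_config(n = 15), seed = 11)
#' screen_scorecard(scn)$correct_confirmed
#' @export
screen_scorecard <- function(scn, carry_neutrals = 1L, alpha = 0.05,
                             qc = qc_control(), min_n = 10L,
                             mode = c("interaction", "fa10a")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scn, "screen_scenario"))
  prim_sim <- simulate_screen(scn)
  primary <- run_screen(prim_sim$layouts, prim_sim$samples,
                        stage = "primary", alpha = alpha, qc = qc,
                        min_n = min_n, mode = mode)
  hits <- primary$deficiency[!is.na(primary$classification) &
                             primary$classification %in%
                               c("decreasing", "enhancing")]
  carried <- character(0)
  for (sid in unique(scn$truth$series)) {
    pool <- scn$truth$deficiency[scn$truth$series == sid &
                                 !scn$truth$lethal &
                                 !scn$truth$deficiency %in% hits]
    if (length(pool) && carry_neutrals > 0L) {
      set.seed(hash_seed(scn$seed, "carry", sid))
      carried <- c(carried,
                   sample(pool, min(carry_neutrals, length(pool))))
    }
  }
  retest <- union(hits, carried)
  if (!length(retest)) {
    return(list(confirmed = data.frame(), truth = scn$truth,
                n_planted = sum(scn$truth$fold != 1 & !scn$truth$lethal),
                correct_confirmed = 0L, false_confirmed = 0L,
                sensitivity = NA_real_, primary = primary,
                secondary = NULL))
  }
  sec_sim <- simulate_secondary(scn, retest)
  secondary <- run_screen(sec_sim$layouts, sec_sim$samples,
                          stage = "secondary", alpha = alpha, qc = qc,
                          min_n = min_n, mode = mode)
  agg <- aggregate_two_stage(primary, secondary, alpha = alpha)
  conf <- agg$confirmed
  truth <- scn$truth
  planted <- truth$deficiency[truth$fold != 1 & !truth$lethal]
  truth_class <- stats::setNames(truth$class, truth$deficiency)
  correct <- sum(conf$deficiency %in% planted &
                 conf$classification == truth_class[conf$deficiency])
  false_conf <- sum(truth_class[conf$deficiency] == "neutral")
  list(confirmed = conf, truth = truth, n_planted = length(planted),
       correct_confirmed = correct, false_confirmed = false_conf,
       sensitivity = if (length(planted)) correct / length(planted)
                     else NA_real_,
       primary = primary, secondary = secondary)
}
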