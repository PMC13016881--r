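make_layout_samples <- function(n_def = 3, n = 12, seed = 1,
                                fold = rep(1, n_def)) {
  samples <- list()
  samples[["POS"]] <- simulate_sample(n = n, sigma_fa = 10, seed = seed,
                                      genotype = "POS")
  labs <- sprintf("D%02d+TG", seq_len(n_def))
  for (k in seq_len(n_def)) {
    samples[[labs[k]]] <- simulate_sample(n = n,
                                          sigma_fa = 10 * sqrt(fold[k]),
                                          seed = seed + k,
                                          genotype = labs[k])
  }
  layout <- series_layout("S1",
                          experimental = setNames(labs,
                                                  sprintf("D%02d", seq_len(n_def))),
                          positive_control = "POS")
  list(layout = layout, samples = samples)
}

test_that("Holm adjustment reproduces the worked example and its properties", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  set.seed(10)
  p <- runif(25)
  a <- holm_adjust(p)
  expect_true(all(a >= p))
  expect_equal(order(a[order(p)]), seq_along(p))  # order preserving
  expect_error(holm_adjust(c(0.5, 1.2)))
})

test_that("classification follows the adjusted-p / fold-change rule", {
  expect_equal(classify_comparison(0.0468, 0.37329), "decreasing")
  expect_equal(classify_comparison(0.00434, 3.67005), "enhancing")
  expect_equal(classify_comparison(0.2, 2.0), "neutral")
  expect_equal(classify_comparison(0.01, NA), "neutral")
  expect_equal(classify_comparison(0.06, 0.2, alpha = 0.05), "neutral")
  expect_equal(classify_comparison(0.04, 0.2, alpha = 0.01), "neutral")
})

test_that("a series tested against itself is entirely neutral with F = 1", {
  pos <- simulate_sample(n = 12, sigma_fa = 10, seed = 3, genotype = "POS")
  samples <- list(POS = pos)
  labs <- c("D01+TG", "D02+TG")
  for (lab in labs) {
    s <- pos
    s$genotype <- lab
    s$data$genotype <- lab
    samples[[lab]] <- s
  }
  layout <- series_layout("S1", experimental = setNames(labs, c("D01", "D02")),
                          positive_control = "POS")
  res <- run_series(layout, samples, qc = NULL)
  expect_equal(res$f, c(1, 1))
  expect_equal(res$p_raw, c(1, 1))
  expect_equal(res$fold_change, c(1, 1))
  expect_true(all(res$classification == "neutral"))
})

test_that("missing or tiny genotypes are scored lethal; missing control aborts", {
  ls <- make_layout_samples(n_def = 3, seed = 7)
  ls$samples[["D02+TG"]] <- NULL
  ls$samples[["D03+TG"]] <- simulate_sample(n = 5, seed = 8,
                                            genotype = "D03+TG")
  res <- run_series(ls$layout, ls$samples, qc = NULL, min_n = 10)
  expect_equal(res$classification[res$deficiency == "D02"], "lethal")
  expect_equal(res$classification[res$deficiency == "D03"], "lethal")
  expect_false(is.na(res$p_raw[res$deficiency == "D01"]))
  # Holm family covers only the tested rows
  expect_equal(res$p_adj[res$deficiency == "D01"],
               res$p_raw[res$deficiency == "D01"])

  bad <- ls$layout
  bad$positive_control <- "NOPE"
  expect_error(run_series(bad, ls$samples), "positive control")
})

test_that("a planted strong enhancer is the only non-neutral call", {
  ls <- make_layout_samples(n_def = 8, n = 30, seed = 42,
                            fold = c(1, 1, 25, 1, 1, 1, 1, 1))
  res <- run_series(ls$layout, ls$samples)
  expect_equal(res$classification[res$deficiency == "D03"], "enhancing")
  expect_true(all(res$classification[res$deficiency != "D03"] == "neutral"))
  expect_gt(res$fold_change[res$deficiency == "D03"], 1)
})

test_that("the secondary stage adds its own Holm family for df-alone effects", {
  scn <- screen_scenario(n_series = 1, per_series = 4,
                         planted = c(Df002 = 6),
                         df_alone_fold = c(Df003 = 30),
                         baseline = sim_config(n = 20, sigma_fa = sqrt(50) * 3),
                         seed = 77)
  sec <- simulate_secondary(scn, scn$truth$deficiency)
  res <- run_series(sec$layouts[[1]], sec$samples, stage = "secondary",
                    qc = NULL)
  expect_true(all(c("alone_p_adj", "alone_fold") %in% names(res)))
  expect_true(all(res$alone_p_adj >= res$alone_p_raw, na.rm = TRUE))
  # the planted df-alone effect is significant and the strongest in its family
  expect_lt(res$alone_p_adj[res$deficiency == "Df003"], 0.05)
  expect_equal(which.min(res$alone_p_adj), match("Df003", res$deficiency))
  # and the df-alone family never affects the main classification columns
  expect_false(any(is.na(res$p_adj)))
})

test_that("two-stage aggregation keeps only direction-consistent repeats", {
  row <- function(def, cls, fold, p) {
    data.frame(deficiency = def, classification = cls, fold_change = fold,
               p_adj = p, stringsAsFactors = FALSE)
  }
  primary <- rbind(row("A", "decreasing", 0.3, 0.01),
                   row("B", "enhancing", 4, 0.02),
                   row("C", "enhancing", 3, 0.01),
                   row("D", "neutral", 1.2, 0.8))
  secondary <- rbind(row("A", "decreasing", 0.4, 0.03),
                     row("B", "neutral", 1.5, 0.4),
                     row("C", "decreasing", 0.5, 0.01),
                     row("D", "neutral", 0.9, 0.9),
                     row("E", "enhancing", 5, 0.001))
  agg <- aggregate_two_stage(primary, secondary)
  expect_equal(agg$confirmed$deficiency, "A")
  expect_equal(agg$confirmed$classification, "decreasing")
  expect_equal(agg$unconfirmable, "E")
})

test_that("screen results are invariant to unrelated series composition", {
  # the same deficiency sample compared with the same control must yield the
  # same raw statistics whatever else sits in the series; only the Holm
  # family (and so adjusted p) may change
  ls_small <- make_layout_samples(n_def = 2, n = 15, seed = 5,
                                  fold = c(9, 1))
  ls_big <- make_layout_samples(n_def = 6, n = 15, seed = 5,
                                fold = c(9, 1, 1, 1, 1, 1))
  r_small <- run_series(ls_small$layout, ls_small$samples, qc = NULL)
  r_big <- run_series(ls_big$layout, ls_big$samples, qc = NULL)
  expect_equal(r_small$f[1:2], r_big$f[1:2])
  expect_equal(r_small$p_raw[1:2], r_big$p_raw[1:2])
  expect_equal(r_small$fold_change[1:2], r_big$fold_change[1:2])
})
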