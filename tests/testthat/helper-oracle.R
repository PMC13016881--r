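# Brute-force oracles and small fixture builders, independent of the
# package's vectorized code paths.

# Explicit-loop sums-of-squares decomposition of a balanced two-way block:
# every marginal/cell mean is computed by direct averaging over subsets, and
# squared deviations are accumulated stratum by stratum.
oracle_anova <- function(df) {
  ids <- sort(unique(df$individual))
  sides <- c("L", "R")
  n <- length(ids)
  r <- nrow(df) / (2 * n)
  grand <- mean(df$length)
  ss_side <- 0; ss_ind <- 0; ss_int <- 0; ss_res <- 0
  for (s in sides) {
    ms <- mean(df$length[df$side == s])
    ss_side <- ss_side + n * r * (ms - grand)^2
  }
  for (i in ids) {
    mi <- mean(df$length[df$individual == i])
    ss_ind <- ss_ind + 2 * r * (mi - grand)^2
    for (s in sides) {
      cell <- df$length[df$individual == i & df$side == s]
      mc <- mean(cell)
      ms <- mean(df$length[df$side == s])
      ss_int <- ss_int + r * (mc - mi - ms + grand)^2
      for (v in cell) ss_res <- ss_res + (v - mc)^2
    }
  }
  list(ms = c(side = ss_side / 1,
              individual = ss_ind / (n - 1),
              interaction = ss_int / (n - 1),
              residual = ss_res / (n * 2 * (r - 1))),
       ss = c(side = ss_side, individual = ss_ind,
              interaction = ss_int, residual = ss_res))
}

# Hand-built balanced block from an (n x 2 x r) value array.
make_block <- function(values, genotype = "g", series = "s") {
  n <- dim(values)[1]; r <- dim(values)[3]
  rows <- expand.grid(replicate = seq_len(r), side = c("L", "R"),
                      individual = sprintf("i%02d", seq_len(n)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("individual", "side", "replicate")]
  rows$genotype <- genotype
  rows$series <- series
  idx <- cbind(match(rows$individual, sprintf("i%02d", seq_len(n))),
               match(rows$side, c("L", "R")),
               rows$replicate)
  rows$length <- values[idx]
  rows[, c("individual", "genotype", "series", "side", "replicate", "length")]
}

random_block_df <- function(n, r, mu = 100, sd = 5) {
  make_block(array(rnorm(n * 2 * r, mu, sd), dim = c(n, 2, r)))
}
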