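test_that("measurement tables survive a write/read round trip", {
  s <- simulate_sample(n = 6, r = 2, seed = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(s$data, path)
  back <- read_measurements(path)
  expect_equal(back[setdiff(names(back), "length")],
               s$data[setdiff(names(s$data), "length")])
  expect_equal(back$length, s$data$length, tolerance = 1e-12)
  # idempotence: a second write/read reproduces the same table
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("side tokens are normalized and bad input is rejected by name", {
  d <- make_block(array(1:8 + 10, dim = c(2, 2, 2)))
  d$side <- ifelse(d$side == "L", "left", "Right")
  d$side[1] <- "l"
  m <- as_measurements(d)
  expect_setequal(unique(m$side), c("L", "R"))
  expect_equal(sum(m$side == "L"), 4L)

  d2 <- d; d2$side[1] <- "top"
  expect_error(as_measurements(d2), "top")

  d3 <- make_block(array(1:8 + 10, dim = c(2, 2, 2)))
  d3$length[3] <- 0
  expect_error(as_measurements(d3), d3$individual[3])

  d4 <- make_block(array(1:8 + 10, dim = c(2, 2, 2)))
  d4$replicate[2] <- 1L   # duplicates (i01, L, 1)
  expect_error(as_measurements(d4), "duplicate")

  expect_error(as_measurements(d[, -6]), "length")
})

test_that("column mapping renames dialect columns", {
  d <- make_block(array(rnorm(12, 50), dim = c(3, 2, 2)))
  names(d)[names(d) == "length"] <- "wing_len"
  m <- as_measurements(d, col_map = c(length = "wing_len"))
  expect_true("length" %in% names(m))
  expect_error(as_measurements(d, col_map = c(size = "wing_len")), "unknown")
  expect_error(as_measurements(d, col_map = c(length = "nope")), "nope")
})

test_that("assemble_samples builds balanced blocks and reports exclusions", {
  d <- make_block(array(rnorm(16, 100), dim = c(4, 2, 2)))
  d <- d[!(d$individual == "i04" & d$side == "R"), ]  # i04 missing its R side
  samples <- assemble_samples(d)
  expect_length(samples, 1L)
  s <- samples[[1]]
  expect_equal(s$n, 3L)
  expect_equal(s$r, 2L)
  ex <- attr(samples, "excluded")
  expect_equal(ex$individual, "i04")
  # record conservation: retained + excluded rows account for every input row
  expect_equal(nrow(s$data) + sum(d$individual %in% ex$individual), nrow(d))
})

test_that("assemble_samples handles empty input and rejects mixed r", {
  empty <- data.frame(individual = character(), genotype = character(),
                      series = character(), side = character(),
                      replicate = integer(), length = numeric())
  out <- assemble_samples(empty)
  expect_length(out, 0L)
  expect_equal(nrow(attr(out, "excluded")), 0L)

  a <- make_block(array(rnorm(8, 10), dim = c(2, 2, 2)))
  b <- make_block(array(rnorm(12, 10), dim = c(2, 2, 3)))
  b$individual <- sub("^i", "j", b$individual)
  expect_error(assemble_samples(rbind(a, b)), "mixed r")
})

test_that("simulator output assembles losslessly", {
  s <- simulate_sample(n = 7, r = 3, seed = 5, genotype = "gA")
  t <- simulate_sample(n = 5, r = 3, seed = 6, genotype = "gB")
  samples <- assemble_samples(rbind(s$data, t$data))
  expect_length(samples, 2L)
  expect_equal(nrow(attr(samples, "excluded")), 0L)
  expect_equal(unname(sort(vapply(samples, function(x) x$n, 1L))), c(5L, 7L))
  expect_true(all(vapply(samples, function(x) x$r, 1L) == 3L))
})

test_that("landmark length is the Euclidean distance and is rigid-motion invariant", {
  lm <- data.frame(landmark = c(3, 13), x = c(0, 3), y = c(0, 4))
  expect_equal(landmark_length(lm), 5)
  expect_equal(landmark_length(data.frame(landmark = c(3, 13),
                                          x = c(1, 1), y = c(2, 2))), 0)
  expect_error(landmark_length(data.frame(landmark = 3, x = 0, y = 0),
                               id = "i07"), "13.*i07")

  set.seed(42)
  for (k in 1:50) {
    p <- matrix(rnorm(4), 2)
    lm <- data.frame(landmark = c(3, 13), x = p[, 1], y = p[, 2])
    expect_equal(landmark_length(lm),
                 sqrt(sum((p[1, ] - p[2, ])^2)), tolerance = 1e-12)
    # translation + rotation leave the distance unchanged
    th <- runif(1, 0, 2 * pi); shift <- rnorm(2, 0, 10)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    q <- sweep(p %*% t(rot), 2, -shift)
    expect_equal(landmark_length(data.frame(landmark = c(3, 13),
                                            x = q[, 1], y = q[, 2])),
                 landmark_length(lm), tolerance = 1e-9)
  }
})

test_that("landmark tables collapse to measurement tables", {
  base <- expand.grid(individual = c("a", "b"), side = c("L", "R"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  lm <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    data.frame(base[i, ], genotype = "g", series = "s",
               landmark = c(3, 13),
               x = c(0, 30 + i), y = c(0, 0), row.names = NULL)
  }))
  m <- landmarks_to_measurements(lm)
  expect_equal(nrow(m), 8L)
  expect_true(all(m$length > 30))
  expect_s3_class(assemble_samples(m)[[1]], "genotype_sample")
})

test_that("deficiency metadata is validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(name = c("Df1", "Df2"), arm = "2L",
                   cytology_start = "22A1", cytology_end = "22B2",
                   span = c(100, 200), background = "unknown")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_deficiencies(path)$name, c("Df1", "Df2"))
  df$name <- "Df1"
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_deficiencies(path), "duplicate")
})
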