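## Tabular input/output and balanced-block assembly.
##
## The canonical measurement table is long ("tidy"): one row per replicate
## measurement of one side of one individual, with columns
##   individual, genotype, series, side (L/R), replicate (>= 1), length (> 0).
## A column-name mapping accommodates other dialects.

.required_cols <- c("individual", "genotype", "series", "side", "replicate", "length")

#' Read a long-format measurement table
#'
#' Reads a CSV/TSV of repeated left/right measurements into the canonical
#' long format. Side tokens are normalized (`l`, `left`, `L` to `"L"`;
#' likewise for `R`). Rows with non-positive length and duplicated
#' (individual, side, replicate) keys are fatal errors that name the
#' offending individuals.
#'
#' @param path Path to a delimited text file with a header.
#' @param col_map Optional named character vector mapping canonical column
#'   names (`individual`, `genotype`, `series`, `side`, `replicate`,
#'   `length`) to the names used in the file, e.g.
#'   `c(length = "wing_len")`. Unmapped columns keep canonical names.
#' @param sep Field separator; defaults to `","` unless the file extension is
#'   `.tsv`/`.txt`, in which case tab.
#' @return A `data.frame` with the six canonical columns, rows in file order.
#' @seealso [write_measurements()], [assemble_samples()]
#' @export
read_measurements <- function(path, col_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_measurements(raw, col_map = col_map)
}

#' Coerce a data frame to the canonical measurement table
#'
#' Validates and normalizes an in-memory table: applies a column mapping,
#' normalizes side tokens, and enforces the invariants (positive lengths,
#' unique (individual, side, replicate) keys).
#'
#' @inheritParams read_measurements
#' @param x A data frame containing the six required columns (possibly under
#'   mapped names).
#' @return A validated `data.frame` with canonical columns.
#' @export
as_measurements <- function(x, col_map = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), .required_cols)
    if (length(bad))
      stop("unknown canonical column(s) in col_map: ", paste(bad, collapse = ", "))
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(x))
        stop("mapped column not in table: ", col_map[[canon]])
      names(x)[names(x) == col_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(.required_cols, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  x <- x[.required_cols]
  x$individual <- as.character(x$individual)
  x$genotype   <- as.character(x$genotype)
  x$series     <- as.character(x$series)
  x$side       <- normalize_side(x$side)
  x$replicate  <- as.integer(x$replicate)
  x$length     <- as.numeric(x$length)
  if (anyNA(x$replicate) || any(x$replicate < 1L))
    stop("replicate must be an integer >= 1")
  bad_len <- is.na(x$length) | x$length <= 0
  if (any(bad_len))
    stop("non-positive or missing length for individual(s): ",
         paste(unique(x$individual[bad_len]), collapse = ", "))
  key <- paste(x$individual, x$side, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(x$individual[duplicated(key)])
    stop("duplicate (individual, side, replicate) records for: ",
         paste(dup, collapse = ", "))
  }
  rownames(x) <- NULL
  x
}

## "l"/"left"/"L" -> "L"; "r"/"right"/"R" -> "R"; anything else is fatal.
normalize_side <- function(side) {
  s <- tolower(trimws(as.character(side)))
  out <- ifelse(s %in% c("l", "left"), "L",
         ifelse(s %in% c("r", "right"), "R", NA_character_))
  if (anyNA(out))
    stop("unrecognized side token(s): ",
         paste(unique(side[is.na(out)]), collapse = ", "))
  out
}

#' Write a measurement table
#'
#' Writes the canonical long format as CSV (UTF-8, dot decimal separator),
#' the inverse of [read_measurements()]: a write/read round trip returns an
#' identical record collection.
#'
#' @param x A measurement `data.frame` (validated via [as_measurements()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  x <- as_measurements(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Euclidean distance between two landmarks
#'
#' Extracts a linear size measurement from a 2-D landmark configuration as
#' the distance between two landmark indices. For wing length the
#' conventional choice is the span between landmarks 3 and 13.
#'
#' @param landmarks A data frame with columns `landmark`, `x`, `y` (one
#'   digitized configuration), or a two-column matrix whose rownames are
#'   landmark indices.
#' @param from,to Landmark indices to span (defaults 3 and 13).
#' @param id Optional identifier used in error messages.
#' @return The Euclidean distance (non-negative scalar).
#' @export
landmark_length <- function(landmarks, from = 3, to = 13, id = NULL) {
  if (is.matrix(landmarks)) {
    landmarks <- data.frame(landmark = as.numeric(rownames(landmarks)),
                            x = landmarks[, 1], y = landmarks[, 2])
  }
  who <- if (is.null(id)) "" else paste0(" (individual ", id, ")")
  i <- match(from, landmarks$landmark)
  j <- match(to, landmarks$landmark)
  if (is.na(i) || is.na(j))
    stop("landmark ", if (is.na(i)) from else to, " absent", who)
  sqrt((landmarks$x[i] - landmarks$x[j])^2 + (landmarks$y[i] - landmarks$y[j])^2)
}

#' Read a long-format landmark table
#'
#' @param path Path to a delimited file with columns `individual`,
#'   `genotype`, `series`, `side`, `replicate`, `landmark`, `x`, `y`.
#' @param sep Field separator, inferred from the extension by default.
#' @return A `data.frame` with those eight columns, sides normalized.
#' @seealso [landmarks_to_measurements()]
#' @export
read_landmarks <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("individual", "genotype", "series", "side", "replicate",
            "landmark", "x", "y")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  x$side <- normalize_side(x$side)
  x[need]
}

#' Convert landmark configurations to length measurements
#'
#' Collapses each (individual, side, replicate) landmark configuration to a
#' single linear measurement via [landmark_length()].
#'
#' @param lm A landmark table as returned by [read_landmarks()].
#' @inheritParams landmark_length
#' @return A canonical measurement `data.frame`.
#' @export
landmarks_to_measurements <- function(lm, from = 3, to = 13) {
  key <- interaction(lm$individual, lm$genotype, lm$series, lm$side,
                     lm$replicate, drop = TRUE, lex.order = TRUE)
  pieces <- split(lm, key)
  rows <- lapply(pieces, function(g) {
    data.frame(individual = g$individual[1], genotype = g$genotype[1],
               series = g$series[1], side = g$side[1],
               replicate = g$replicate[1],
               length = landmark_length(g[c("landmark", "x", "y")],
                                        from = from, to = to,
                                        id = g$individual[1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  as_measurements(out)
}

#' Read deficiency metadata
#'
#' Reads a tab-separated table of chromosomal deficiencies: `name`, `arm`,
#' `cytology_start`, `cytology_end`, `span` (length in bp or cytological
#' bands — the downstream correlation is unit-free), `background`.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`; deficiency names are checked unique.
#' @export
read_deficiencies <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "arm", "cytology_start", "cytology_end", "span", "background")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(x$name))
    stop("duplicate deficiency name(s): ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "))
  if (any(!is.na(x$span) & x$span < 0)) stop("span must be non-negative")
  x[need]
}

#' Assemble balanced genotype samples from a measurement table
#'
#' Groups measurements by (genotype, series) and builds one balanced block
#' per group: `n` individuals x 2 sides x `r` replicates. The replicate
#' count `r` is inferred as the modal per-(individual, side) record count of
#' the group; individuals without exactly `r` records on each of both sides
#' are excluded (never imputed) and reported in the `"excluded"` attribute.
#' A group left with fewer than two individuals is flagged unusable.
#'
#' @param x A measurement `data.frame` (validated via [as_measurements()]).
#' @return A named list of `genotype_sample` objects (names
#'   `"genotype@series"`), with attribute `"excluded"`: a data frame of
#'   excluded individuals and reasons.
#' @examples
#' d <- simulate_sample(n = 5, seed = 1)$data
#' samples <- assemble_samples(d)
#' attr(samples, "excluded")  # empty for complete simulated data
#' @export
assemble_samples <- function(x) {
  x <- as_measurements(x)
  key <- paste(x$genotype, x$series, sep = "@")
  groups <- split(x, key)
  excluded <- list()
  samples <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    cnt <- table(g$individual, g$side)
    per_side <- as.vector(cnt[cnt > 0])
    tab <- table(per_side)
    modal <- as.integer(names(tab)[tab == max(tab)])
    if (length(modal) > 1L)
      stop("cannot infer a single replicate count for sample ", k,
           ": mixed r (", paste(modal, collapse = " vs "), ")")
    r <- modal
    ids <- rownames(cnt)
    complete <- ids[apply(cnt, 1L, function(z)
      length(z) == 2L && all(z == r))]
    dropped <- setdiff(ids, complete)
    if (length(dropped))
      excluded[[k]] <<- data.frame(genotype = g$genotype[1],
                                   series = g$series[1],
                                   individual = dropped,
                                   reason = "incomplete block",
                                   stringsAsFactors = FALSE)
    keep <- g[g$individual %in% complete, , drop = FALSE]
    new_genotype_sample(keep, genotype = g$genotype[1], series = g$series[1],
                        r = r)
  })
  names(samples) <- names(groups)
  structure(samples,
            excluded = if (length(excluded)) {
              ex <- do.call(rbind, excluded); rownames(ex) <- NULL; ex
            } else {
              data.frame(genotype = character(), series = character(),
                         individual = character(), reason = character(),
                         stringsAsFactors = FALSE)
            })
}

## Construct a genotype_sample from a complete-block data frame.
## Stores both the ordered long table and a (n x 2 x r) array for fast ANOVA.
new_genotype_sample <- function(data, genotype, series, r) {
  data <- data[order(data$individual, data$side, data$replicate), , drop = FALSE]
  rownames(data) <- NULL
  ids <- unique(data$individual)
  n <- length(ids)
  y <- array(NA_real_, dim = c(n, 2L, r),
             dimnames = list(ids, c("L", "R"), NULL))
  if (n > 0L) {
    ## ordered by (individual, side, replicate): fill replicate-fastest
    y[] <- aperm(array(data$length, dim = c(r, 2L, n)), c(3L, 2L, 1L))
  }
  structure(list(genotype = genotype, series = series, n = n, r = r,
                 individuals = ids, y = y, data = data),
            class = "genotype_sample")
}

#' @export
print.genotype_sample <- function(x, ...) {
  cat("Genotype sample: ", x$genotype, " (series ", x$series, ")\n", sep = "")
  cat("  n = ", x$n, " individuals x 2 sides x r = ", x$r,
      " replicates\n", sep = "")
  if (x$n < 2L) cat("  [unusable: fewer than 2 individuals]\n")
  invisible(x)
}

#' Is a sample usable for ANOVA?
#'
#' A sample supports the two-way decomposition when it has at least two
#' individuals (so the individual-by-side interaction has at least one
#' degree of freedom) and at least two replicates per side (so measurement
#' error is separable).
#'
#' @param sample A `genotype_sample`.
#' @return Logical scalar.
#' @export
is_usable <- function(sample) {
  inherits(sample, "genotype_sample") && sample$n >= 2L && sample$r >= 2L
}
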