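#' Triplet datasets
#'
#' A triplet records one similarity trial: the observer judged stimulus
#' `near` as more similar to the `anchor` stimulus than stimulus `far`.
#' A dataset is an ordered collection of such trials over `n_stimuli`
#' stimuli.  Duplicated rows are legitimate data (repeated trials of the
#' same question carry information about response consistency) and are
#' kept as-is.
#'
#' Indices are 1-based in memory, following R convention.  On disk the
#' canonical triplet file uses 0-based indices (see [read_triplets()]).
#'
#' @param triplets an m x 3 matrix or data frame of stimulus indices with
#'   columns anchor, near, far (1-based).
#' @param n_stimuli number of stimuli; defaults to the largest index
#'   observed.  May be larger than that (stimuli never referenced by any
#'   triplet are allowed and get embedded anyway).
#' @return an object of class `triplet_dataset`: a list with elements
#'   `triplets` (integer matrix, columns anchor/near/far) and `n_stimuli`.
#' @examples
#' td <- triplet_dataset(rbind(c(2, 1, 3), c(3, 1, 2)))
#' n_triplets(td)
#' @export
triplet_dataset <- function(triplets, n_stimuli = NULL) {
  if (is.data.frame(triplets)) triplets <- as.matrix(triplets)
  if (is.vector(triplets) && length(triplets) == 3L) {
    triplets <- matrix(triplets, nrow = 1L)
  }
  if (!is.matrix(triplets) || ncol(triplets) != 3L) {
    stop_input("`triplets` must be an m x 3 matrix (anchor, near, far)")
  }
  if (!is.numeric(triplets) || any(!is.finite(triplets)) ||
      any(triplets != round(triplets))) {
    stop_input("triplet indices must be finite integers")
  }
  storage.mode(triplets) <- "integer"
  if (any(triplets < 1L)) {
    stop_input("triplet indices must be >= 1 (1-based in memory)")
  }
  dup <- triplets[, 1L] == triplets[, 2L] | triplets[, 1L] == triplets[, 3L] |
    triplets[, 2L] == triplets[, 3L]
  if (any(dup)) {
    stop_input("indices within a triplet must be distinct (first bad row: ",
               which(dup)[1L], ")")
  }
  max_idx <- if (nrow(triplets)) max(triplets) else 0L
  if (is.null(n_stimuli)) n_stimuli <- max_idx
  n_stimuli <- as.integer(n_stimuli)
  if (length(n_stimuli) != 1L || is.na(n_stimuli) || n_stimuli < max_idx) {
    stop_input("`n_stimuli` must be a single integer >= the largest index (",
               max_idx, ")")
  }
  colnames(triplets) <- c("anchor", "near", "far")
  structure(list(triplets = triplets, n_stimuli = n_stimuli),
            class = "triplet_dataset")
}

#' @rdname triplet_dataset
#' @param x a `triplet_dataset`.
#' @export
n_triplets <- function(x) {
  stopifnot(inherits(x, "triplet_dataset"))
  nrow(x$triplets)
}

#' @export
print.triplet_dataset <- function(x, ...) {
  cat("Triplet dataset:", n_triplets(x), "triplets over", x$n_stimuli,
      "stimuli\n")
  if (n_triplets(x)) {
    print(head(x$triplets, 5L))
    if (n_triplets(x) > 5L) cat("...\n")
  }
  invisible(x)
}

# Subset the trials of a dataset, keeping n_stimuli.
subset_triplets <- function(data, idx) {
  triplet_dataset(data$triplets[idx, , drop = FALSE],
                  n_stimuli = data$n_stimuli)
}

#' Perceptual scales
#'
#' A scale assigns each of n stimuli a coordinate in d dimensions; the
#' Euclidean distances between coordinates model perceived dissimilarity.
#' Triplet judgments constrain the scale only ordinally, so it is
#' recoverable at best up to similarity transformations (translation,
#' rotation, reflection, uniform scaling).
#'
#' @param coordinates an n x d numeric matrix (rows = stimuli); a vector is
#'   treated as a 1-dimensional scale.
#' @return an object of class `perceptual_scale` (a numeric matrix).
#' @examples
#' s <- perceptual_scale(c(0, 1, 3))
#' scale_dim(s)
#' @export
perceptual_scale <- function(coordinates) {
  if (is.vector(coordinates) && is.numeric(coordinates)) {
    coordinates <- matrix(coordinates, ncol = 1L)
  }
  if (!is.matrix(coordinates) || !is.numeric(coordinates)) {
    stop_input("`coordinates` must be a numeric matrix")
  }
  if (any(!is.finite(coordinates))) {
    stop_input("scale coordinates must all be finite")
  }
  if (nrow(coordinates) < 1L || ncol(coordinates) < 1L) {
    stop_input("a scale needs at least one stimulus and one dimension")
  }
  structure(coordinates, class = c("perceptual_scale", class(coordinates)))
}

#' @rdname perceptual_scale
#' @param x a `perceptual_scale`.
#' @export
scale_dim <- function(x) ncol(x)

#' @rdname perceptual_scale
#' @export
n_stimuli <- function(x) nrow(x)

#' @export
print.perceptual_scale <- function(x, ...) {
  cat("Perceptual scale:", nrow(x), "stimuli in", ncol(x), "dimension(s)\n")
  print(head(unclass(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

check_indices <- function(scale, data) {
  bad <- data$triplets > nrow(scale)
  if (any(bad)) {
    stop_input("stimulus index ", max(data$triplets[bad]),
               " out of range for a scale of ", nrow(scale), " stimuli")
  }
}

# Euclidean distances between scale rows indexed by a and b (vectors).
row_dist <- function(scale, a, b) {
  diff <- scale[a, , drop = FALSE] - scale[b, , drop = FALSE]
  sqrt(rowSums(diff * diff))
}

#' Triplet agreement
#'
#' A triplet (anchor, near, far) agrees with a scale when
#' `dist(near, anchor) <= dist(anchor, far)`.  Ties (exact equality) count
#' as agreement, matching the `<=` of the agreement inequality.
#'
#' @param scale a [perceptual_scale()].
#' @param data a [triplet_dataset()] (or anything coercible via
#'   [triplet_dataset()]).
#' @return a logical vector, one entry per triplet.
#' @examples
#' s <- perceptual_scale(c(0, 1, 3))
#' agrees(s, triplet_dataset(c(2, 1, 3)))
#' @export
agrees <- function(scale, data) {
  if (!inherits(data, "triplet_dataset")) data <- triplet_dataset(data)
  check_indices(scale, data)
  t <- data$triplets
  row_dist(scale, t[, "near"], t[, "anchor"]) <=
    row_dist(scale, t[, "anchor"], t[, "far"])
}

#' Triplet accuracy
#'
#' The proportion of triplets in a dataset that agree with a scale:
#' the fraction of trials where `dist(near, anchor) <= dist(anchor, far)`.
#' Ranges from 0 (full disagreement) to 1 (full agreement).  Computed on
#' the triplets used to fit a scale it is the training accuracy; on
#' held-out triplets it is the test accuracy, the quantity the
#' dimension-selection procedure works with.
#'
#' @inheritParams agrees
#' @return a number in \[0, 1\].
#' @examples
#' s <- perceptual_scale(c(0, 1, 3))
#' triplet_accuracy(s, triplet_dataset(rbind(c(2, 1, 3), c(2, 3, 1))))
#' @export
triplet_accuracy <- function(scale, data) {
  if (!inherits(data, "triplet_dataset")) data <- triplet_dataset(data)
  if (n_triplets(data) == 0L) {
    stop_input("cannot compute accuracy of an empty dataset")
  }
  mean(agrees(scale, data))
}

#' Read and write triplet files
#'
#' The canonical triplet file is plain delimited text with three integer
#' columns `anchor,near,far`, one trial per row, 0-based stimulus indices,
#' an optional header line, and either comma or whitespace as delimiter
#' (auto-detected).
#'
#' @param path file path.
#' @param n_stimuli optional override for the stimulus count; defaults to
#'   1 + the largest index in the file.
#' @return [read_triplets()] returns a [triplet_dataset()];
#'   [write_triplets()] returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_triplets(triplet_dataset(rbind(c(2, 1, 3), c(3, 1, 2))), f)
#' read_triplets(f)
#' @export
read_triplets <- function(path, n_stimuli = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_input("no triplet rows in ", path)
  delim <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else "[[:space:]]+"
  parse_row <- function(line) strsplit(trimws(line), delim)[[1L]]
  first <- parse_row(lines[[1L]])
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  rows <- lines[seq.int(1L + has_header,
                        length.out = length(lines) - has_header)]
  if (!length(rows)) stop_input("no triplet rows in ", path)
  out <- matrix(0L, nrow = length(rows), ncol = 3L)
  for (i in seq_along(rows)) {
    fields <- parse_row(rows[[i]])
    lineno <- i + has_header
    if (length(fields) < 3L) {
      stop_input("line ", lineno, ": expected 3 columns, found ",
                 length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (any(is.na(vals)) || any(vals != round(vals))) {
      stop_input("line ", lineno, ": non-integer field")
    }
    if (anyDuplicated(vals)) {
      stop_input("line ", lineno, ": duplicated index within a row")
    }
    out[i, ] <- as.integer(vals)
  }
  if (any(out < 0L)) stop_input("negative stimulus index (file is 0-based)")
  if (!is.null(n_stimuli)) n_stimuli <- as.integer(n_stimuli)
  triplet_dataset(out + 1L, n_stimuli = n_stimuli)
}

#' @rdname read_triplets
#' @param data a [triplet_dataset()].
#' @export
write_triplets <- function(data, path) {
  stopifnot(inherits(data, "triplet_dataset"))
  if (!nzchar(path)) stop_input("empty output path")
  out <- data$triplets - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("anchor,near,far", con)
  write.table(out, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write scale files
#'
#' A scale file is plain delimited text with one stimulus per row and d
#' numeric columns; the row number (1-based) is the stimulus index.
#'
#' @param path file path.
#' @return [read_scale()] returns a [perceptual_scale()];
#'   [write_scale()] returns `path` invisibly.
#' @export
read_scale <- function(path) {
  x <- as.matrix(utils::read.table(path, header = FALSE, sep = ","))
  dimnames(x) <- NULL
  perceptual_scale(x)
}

#' @rdname read_scale
#' @param scale a [perceptual_scale()].
#' @export
write_scale <- function(scale, path) {
  if (!nzchar(path)) stop_input("empty output path")
  write.table(unclass(scale), path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
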