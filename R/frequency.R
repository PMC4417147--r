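#' Interaction-frequency matrix
#'
#' A symmetric, non-negative `n x n` matrix of 3C/Hi-C interaction
#' frequencies between restriction fragments. The diagonal carries no
#' information for structure inference and is ignored.
#'
#' @param values numeric `n x n` matrix, non-negative. Asymmetric input is
#'   symmetrized by averaging with a warning.
#' @param labels fragment identifiers (default `frag_1 ... frag_n`).
#' @return An object of class `frequency_matrix` with fields `values`,
#'   `labels` and `n`.
#' @export
frequency_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("frequency matrix must be square")
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("frequency matrix has non-finite entries")
  if (any(values < 0)) stop("frequency matrix has negative entries")
  if (max(abs(values - t(values))) > 0) {
    warning("asymmetric frequency matrix; symmetrizing by averaging")
    values <- (values + t(values)) / 2
  }
  n <- nrow(values)
  if (is.null(labels)) labels <- paste0("frag_", seq_len(n))
  if (length(labels) != n) stop("labels length must equal matrix dimension")
  dimnames(values) <- NULL
  structure(list(values = values, labels = as.character(labels), n = n),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  ut <- x$values[upper.tri(x$values)]
  cat(sprintf("Interaction frequency matrix: %d fragments, %d nonzero pairs\n",
              x$n, sum(ut > 0)))
  invisible(x)
}

#' Read an interaction-frequency matrix
#'
#' Two tab-separated dialects are supported. `square`: a header row of
#' fragment labels, then one row per fragment starting with its label
#' followed by `n` numeric frequencies. `triplet`: no header, lines
#' `i<TAB>j<TAB>F` with 1-based fragment indices; absent pairs are zero
#' (`n_fragments` fixes the dimension, otherwise the largest index seen).
#'
#' @param path file path.
#' @param dialect `"square"` or `"triplet"`.
#' @param n_fragments matrix dimension for the triplet dialect (optional).
#' @return A [frequency_matrix()].
#' @export
read_frequency_matrix <- function(path, dialect = c("square", "triplet"),
                                  n_fragments = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("frequency matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty frequency matrix file: ", path)
  if (dialect == "square") {
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    labels <- header[nzchar(header)]
    n <- length(labels)
    if (length(lines) - 1L != n)
      stop("square matrix: header names ", n, " fragments but file has ",
           length(lines) - 1L, " data rows")
    vals <- matrix(0, n, n)
    for (r in seq_len(n)) {
      parts <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1L]]
      if (length(parts) != n + 1L)
        stop("square matrix: ragged row at line ", r + 1L, " (",
             length(parts), " fields, expected ", n + 1L, ")")
      x <- suppressWarnings(as.numeric(parts[-1L]))
      if (any(is.na(x)))
        stop("square matrix: non-numeric cell at line ", r + 1L)
      if (any(x < 0))
        stop("square matrix: negative frequency at line ", r + 1L)
      vals[r, ] <- x
    }
    frequency_matrix(vals, labels)
  } else {
    nmax <- 0L
    recs <- vector("list", length(lines))
    for (k in seq_along(lines)) {
      parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
      if (length(parts) != 3L)
        stop("triplet matrix: expected 3 fields at line ", k)
      i <- suppressWarnings(as.integer(parts[1L]))
      j <- suppressWarnings(as.integer(parts[2L]))
      f <- suppressWarnings(as.numeric(parts[3L]))
      if (is.na(i) || is.na(j) || is.na(f))
        stop("triplet matrix: non-numeric field at line ", k)
      if (i < 1L || j < 1L)
        stop("triplet matrix: indices are 1-based; bad index at line ", k)
      if (f < 0) stop("triplet matrix: negative frequency at line ", k)
      nmax <- max(nmax, i, j)
      recs[[k]] <- c(i, j, f)
    }
    n <- if (is.null(n_fragments)) nmax else as.integer(n_fragments)
    if (nmax > n) stop("triplet matrix: index ", nmax,
                       " exceeds n_fragments = ", n)
    vals <- matrix(0, n, n)
    for (r in recs) {
      vals[r[1L], r[2L]] <- r[3L]
      vals[r[2L], r[1L]] <- r[3L]
    }
    frequency_matrix(vals)
  }
}

#' Write an interaction-frequency matrix (square dialect)
#'
#' @param fm a [frequency_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "frequency_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", fm$labels), collapse = "\t"), con)
  for (r in seq_len(fm$n)) {
    writeLines(paste(c(fm$labels[r],
                       formatC(fm$values[r, ], format = "g", digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
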