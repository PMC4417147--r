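#' Chain model of a chromosome at restriction-fragment resolution
#'
#' A chromosome is represented as a linear chain of `n` genomic segments,
#' one per restriction fragment; each cut site (and the two chromosome
#' ends) is a chain end point, so a model with `n` segments has `n + 1`
#' end points whose 3D coordinates are the object of inference. The rest
#' length of segment `i` is its fiber length at equilibrium,
#' `bp / packing_density / length_scale_nm` reduced units.
#'
#' @param spans integer matrix or data frame with two columns (`start`,
#'   `end`) of 0-based half-open fragment intervals in bp, ordered,
#'   contiguous and non-overlapping.
#' @param chrom chromosome identifier.
#' @param params an [energy_params()] object supplying `packing_density`
#'   and `length_scale_nm`.
#' @return An object of class `segment_model` with fields `chrom`, `spans`,
#'   `bp_lengths`, `rest_lengths` and `n`.
#' @examples
#' m <- segment_model(cbind(c(0, 3900), c(3900, 9100)))
#' m$rest_lengths  # 3900/130/30 = 1.0, 5200/130/30 = 1.333...
#' @export
segment_model <- function(spans, chrom = "chr", params = energy_params()) {
  spans <- as.matrix(spans)
  if (ncol(spans) != 2L) stop("spans must have two columns (start, end)")
  n <- nrow(spans)
  if (n < 2L) stop("a chain model needs at least 2 segments")
  storage.mode(spans) <- "double"
  if (any(!is.finite(spans))) stop("spans contain non-finite values")
  if (any(spans[, 2] <= spans[, 1]))
    stop("every fragment must have end > start")
  if (n > 1L) {
    gap <- which(spans[-1L, 1] != spans[-n, 2])
    if (length(gap))
      stop("fragments must be contiguous; gap/overlap after row ", gap[1L])
  }
  bp <- spans[, 2] - spans[, 1]
  rest <- bp / params$packing_density / params$length_scale_nm
  structure(list(chrom = chrom, spans = unname(spans), bp_lengths = bp,
                 rest_lengths = rest, n = n),
            class = "segment_model")
}

#' Build a segment model from a fragment table
#'
#' Reads a BED-like three-column TSV (chrom, start, end; 0-based half-open,
#' no header) describing the restriction fragments of one chromosome, in
#' order, and returns the corresponding chain model.
#'
#' @param path path to the fragment table, or a data frame with columns
#'   chrom, start, end.
#' @param params an [energy_params()] object.
#' @return A [segment_model()].
#' @export
build_segment_model <- function(path, params = energy_params()) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("fragment table not found: ", path)
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(path)
  }
  if (ncol(tab) < 3L)
    stop("fragment table needs 3 columns: chrom, start, end")
  chrom <- unique(as.character(tab[[1L]]))
  if (length(chrom) != 1L)
    stop("fragment table must describe a single chromosome, found: ",
         paste(chrom, collapse = ", "))
  segment_model(cbind(as.numeric(tab[[2L]]), as.numeric(tab[[3L]])),
                chrom = chrom, params = params)
}

#' @export
print.segment_model <- function(x, ...) {
  cat(sprintf("Segment chain model: %s, %d segments (%d end points), %g bp\n",
              x$chrom, x$n, x$n + 1L, sum(x$bp_lengths)))
  cat(sprintf("  rest lengths: %.3g - %.3g reduced units (total contour %.3g)\n",
              min(x$rest_lengths), max(x$rest_lengths), sum(x$rest_lengths)))
  invisible(x)
}

#' Validate a conformation against a segment model
#'
#' A conformation is a numeric `(n + 1) x 3` matrix of end-point
#' coordinates in reduced length units.
#'
#' @param coords numeric matrix of coordinates.
#' @param model optional [segment_model()]; when given, the point count
#'   must equal `model$n + 1`.
#' @return The validated coordinate matrix.
#' @export
as_conformation <- function(coords, model = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("a conformation has 3 coordinate columns")
  if (nrow(coords) < 2L) stop("a conformation needs at least 2 end points")
  if (any(!is.finite(coords))) stop("conformation has non-finite coordinates")
  if (!is.null(model) && nrow(coords) != model$n + 1L)
    stop("conformation has ", nrow(coords), " points but the model needs ",
         model$n + 1L)
  storage.mode(coords) <- "double"
  unname(coords)
}

#' Segment lengths of a conformation
#'
#' Euclidean distances between consecutive end points.
#'
#' @param coords a conformation matrix (see [as_conformation()]).
#' @return Numeric vector of `n` bond lengths.
#' @examples
#' segment_lengths(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
segment_lengths <- function(coords) {
  coords <- as_conformation(coords)
  d <- diff(coords)
  sqrt(rowSums(d * d))
}
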