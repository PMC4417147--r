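#' Write and read chain structures
#'
#' Structures are stored with coordinates in nm. Two formats are
#' supported: `xyz` (count line, comment line, then `C x y z` records) and
#' `pdb` (a CA pseudo-atom trace, one residue per end point, chain A, with
#' the nm values written into the angstrom coordinate fields). Both
#' round-trip to better than 1e-3 nm.
#'
#' @param coords conformation matrix in reduced units.
#' @param params an [energy_params()] object (supplies `length_scale_nm`).
#' @param path output path.
#' @param format `"xyz"` or `"pdb"`.
#' @return `write_structure` returns `path` invisibly; `read_structure`
#'   returns the conformation matrix in reduced units.
#' @export
write_structure <- function(coords, params = energy_params(), path,
                            format = c("xyz", "pdb")) {
  format <- match.arg(format)
  coords <- as_conformation(coords)
  nm <- coords * params$length_scale_nm
  np <- nrow(nm)
  if (format == "xyz") {
    lines <- c(as.character(np), "chain end points, coordinates in nm",
               sprintf("C %.6f %.6f %.6f", nm[, 1], nm[, 2], nm[, 3]))
  } else {
    lines <- sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(np), seq_len(np), nm[, 1], nm[, 2], nm[, 3])
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path, params = energy_params()) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty structure file: ", path)
  first <- trimws(lines[1L])
  if (grepl("^ATOM", lines[1L])) {
    at <- lines[grepl("^ATOM", lines)]
    nm <- cbind(as.numeric(substr(at, 31, 38)),
                as.numeric(substr(at, 39, 46)),
                as.numeric(substr(at, 47, 54)))
    if (any(is.na(nm))) stop("malformed PDB coordinate field in ", path)
  } else {
    np <- suppressWarnings(as.integer(first))
    if (is.na(np)) stop("malformed structure file (bad count line): ", path)
    if (length(lines) < np + 2L)
      stop("xyz file truncated: expected ", np, " atom records in ", path)
    rec <- strsplit(trimws(lines[3:(np + 2L)]), "[[:space:]]+")
    bad <- which(vapply(rec, length, 1L) != 4L)
    if (length(bad)) stop("malformed xyz record at line ", bad[1L] + 2L)
    nm <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(is.na(nm))) stop("non-numeric xyz coordinate in ", path)
  }
  as_conformation(nm / params$length_scale_nm)
}

#' Write and read a structure ensemble
#'
#' An ensemble directory holds one structure file per member
#' (`member_###.xyz`) plus `weights.tsv` with header
#' `index<TAB>weight<TAB>log_likelihood`. Weights must sum to 1 within
#' 1e-9 on read.
#'
#' @param ensemble an `ensemble_state` (see [ensemble_state()]).
#' @param dir ensemble directory (created if missing).
#' @param params an [energy_params()] object.
#' @return `write_ensemble` returns `dir` invisibly; `read_ensemble`
#'   returns an `ensemble_state`.
#' @export
write_ensemble <- function(ensemble, dir, params = energy_params()) {
  stopifnot(inherits(ensemble, "ensemble_state"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  k <- length(ensemble$conformations)
  for (i in seq_len(k)) {
    write_structure(ensemble$conformations[[i]], params,
                    file.path(dir, sprintf("member_%03d.xyz", i)), "xyz")
  }
  tab <- data.frame(index = seq_len(k),
                    weight = formatC(ensemble$weights, format = "g",
                                     digits = 17),
                    log_likelihood = formatC(ensemble$log_likelihoods,
                                             format = "g", digits = 17))
  write.table(tab, file.path(dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir, params = energy_params()) {
  if (!dir.exists(dir)) stop("ensemble directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "^member_[0-9]+\\.xyz$",
                           full.names = TRUE))
  if (!length(files)) stop("no structure files in ensemble directory ", dir)
  wpath <- file.path(dir, "weights.tsv")
  if (!file.exists(wpath)) stop("missing weights.tsv in ", dir)
  wt <- read.table(wpath, sep = "\t", header = TRUE)
  if (!all(c("index", "weight", "log_likelihood") %in% names(wt)))
    stop("weights.tsv must have columns index, weight, log_likelihood")
  if (nrow(wt) != length(files))
    stop("weights.tsv has ", nrow(wt), " rows but the directory holds ",
         length(files), " structures")
  wt <- wt[order(wt$index), , drop = FALSE]
  if (!identical(as.integer(wt$index), seq_along(files)))
    stop("weights.tsv is missing a row for some structure")
  if (abs(sum(wt$weight) - 1) > 1e-9)
    stop("ensemble weights sum to ", sum(wt$weight), ", not 1")
  confs <- lapply(files, read_structure, params = params)
  ensemble_state(confs, wt$weight, wt$log_likelihood)
}
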