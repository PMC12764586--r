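#' Construct a ContactMatrix
#'
#' A `ContactMatrix` holds a symmetric, non-negative interaction matrix for a
#' single chromosome at a fixed bin resolution. Bin `i` (0-based) covers the
#' half-open bp interval `[i * resolution, (i + 1) * resolution)`.
#'
#' @param values numeric square matrix of interaction frequencies.
#' @param chrom chromosome name.
#' @param resolution bin width in bp (positive integer).
#' @param symmetrize how to handle asymmetric input: `"average"` stores
#'   `(M + t(M)) / 2` (Hi-C maps are symmetric by construction; small
#'   asymmetries in dumps are rounding), `"error"` rejects it.
#' @return an object of class `ContactMatrix` with fields `chrom`,
#'   `resolution`, `n_bins` and `values`.
#' @export
contact_matrix <- function(values, chrom, resolution,
                           symmetrize = c("average", "error")) {
  symmetrize <- match.arg(symmetrize)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("contact matrix must be square, got ", nrow(values), "x", ncol(values))
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("resolution must be a single positive number of bp")
  }
  storage.mode(values) <- "double"
  values[is.na(values)] <- 0
  if (any(!is.finite(values))) stop("contact matrix contains Inf values")
  if (any(values < 0)) stop("contact matrix contains negative values")
  if (!isSymmetric(unname(values), tol = 0)) {
    if (symmetrize == "error") stop("contact matrix is not symmetric")
    values <- (values + t(values)) / 2
  }
  dimnames(values) <- NULL
  structure(
    list(chrom = as.character(chrom), resolution = as.integer(resolution),
         n_bins = nrow(values), values = values),
    class = "ContactMatrix"
  )
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %d bp (%.1f Mb), total signal %.4g\n",
              x$chrom, x$n_bins, x$resolution,
              x$n_bins * x$resolution / 1e6, sum(x$values)))
  invisible(x)
}

#' Read a dense whitespace/TSV Hi-C matrix
#'
#' Parses an `n x n` numeric grid (tab- or whitespace-delimited). `NA`/`NaN`
#' cells are treated as empty (0), mirroring the convention that unmappable
#' bins are left blank in matrix dumps. Asymmetric input is symmetrized as
#' `(M + t(M)) / 2`.
#'
#' @inheritParams contact_matrix
#' @param path file path to the matrix dump.
#' @return a [contact_matrix()] object.
#' @export
read_dense_matrix <- function(path, chrom, resolution) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  rows <- lapply(strsplit(trimws(lines), "[ \t]+"), function(x) {
    suppressWarnings(as.numeric(x))
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop("non-rectangular matrix in ", path, ": row lengths ",
         paste(unique(ncols), collapse = ", "))
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is ", nrow(m), "x", ncol(m), ", expected square")
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative interaction value in ", path)
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' Read a 3-column COO Hi-C matrix
#'
#' Reads sparse triplets `(i, j, count)`. Coordinates are either 0-based bin
#' indices (`coords = "bin"`) or bp starts that must be multiples of the
#' resolution (`coords = "bp"`). Unlisted pairs are 0; both `(i, j)` and
#' `(j, i)` are filled; duplicate records are summed.
#'
#' @inheritParams read_dense_matrix
#' @param coords `"bin"` or `"bp"` coordinate dialect.
#' @param n_bins matrix dimension; inferred as `max(index) + 1` when `NULL`.
#' @return a [contact_matrix()] object.
#' @export
read_coo_matrix <- function(path, chrom, resolution, coords = c("bin", "bp"),
                            n_bins = NULL) {
  coords <- match.arg(coords)
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("numeric", "numeric", "numeric"),
                           col.names = c("i", "j", "count"))
  if (nrow(tab) == 0L && is.null(n_bins)) {
    stop("empty COO file and no n_bins given: ", path)
  }
  if (coords == "bp" && nrow(tab) > 0L) {
    off <- c(tab$i, tab$j) %% resolution
    if (any(off != 0)) {
      stop("bp coordinate not a multiple of resolution ", resolution,
           " in ", path)
    }
    tab$i <- tab$i / resolution
    tab$j <- tab$j / resolution
  }
  if (nrow(tab) > 0L && any(tab$i < 0 | tab$j < 0)) {
    stop("negative bin index in ", path)
  }
  if (any(tab$count < 0)) stop("negative interaction value in ", path)
  n <- if (is.null(n_bins)) max(tab$i, tab$j) + 1L else as.integer(n_bins)
  if (nrow(tab) > 0L && max(tab$i, tab$j) >= n) {
    stop("bin index exceeds n_bins = ", n, " in ", path)
  }
  m <- matrix(0, n, n)
  for (k in seq_len(nrow(tab))) {
    i <- tab$i[k] + 1L; j <- tab$j[k] + 1L
    m[i, j] <- m[i, j] + tab$count[k]
    if (i != j) m[j, i] <- m[j, i] + tab$count[k]
  }
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' Construct a TadSet
#'
#' An ordered, non-overlapping set of half-open genomic intervals (0-based BED
#' convention) on one chromosome, carried as a data.frame with bp and bin
#' coordinates plus provenance (originating sub-matrix window and cluster
#' label, where known).
#'
#' @param start_bin,end_bin integer vectors of half-open bin ranges.
#' @param chrom chromosome name.
#' @param resolution bin width in bp.
#' @param source_window,cluster_label optional integer provenance vectors.
#' @return a `TadSet` (data.frame subclass) sorted by start, with attributes
#'   `chrom` and `resolution`.
#' @export
tad_set <- function(start_bin, end_bin, chrom, resolution,
                    source_window = NA_integer_, cluster_label = NA_integer_) {
  n <- length(start_bin)
  stopifnot(length(end_bin) == n)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start_bp = as.numeric(start_bin) * resolution,
    end_bp = as.numeric(end_bin) * resolution,
    start_bin = as.integer(start_bin),
    end_bin = as.integer(end_bin),
    source_window = rep_len(as.integer(source_window), n),
    cluster_label = rep_len(as.integer(cluster_label), n)
  )
  if (n > 0) {
    if (any(df$end_bin <= df$start_bin)) stop("TAD with end <= start")
    df <- df[order(df$start_bp), , drop = FALSE]
    rownames(df) <- NULL
    if (any(df$start_bp[-1] < df$end_bp[-n])) {
      stop("TadSet intervals overlap")
    }
  }
  structure(df, chrom = as.character(chrom), resolution = as.integer(resolution),
            class = c("TadSet", "data.frame"))
}

#' @export
`[.TadSet` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "chrom") <- attr(x, "chrom")
    attr(out, "resolution") <- attr(x, "resolution")
    class(out) <- class(x)
  }
  out
}

#' Combine TAD tables
#'
#' Row-binds TadSet-shaped data.frames without enforcing the
#' non-overlap invariant (candidate pools from different windows may
#' overlap until stitched).
#'
#' @param ... TadSet-shaped data.frames on the same chromosome/resolution.
#' @return a data.frame with TadSet columns and attributes, sorted by start.
#' @export
bind_tads <- function(...) {
  pieces <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(pieces) == 0L) {
    first <- list(...)[[1]]
    return(first)
  }
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  out <- out[order(out$start_bp, out$source_window), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chrom") <- attr(pieces[[1]], "chrom")
  attr(out, "resolution") <- attr(pieces[[1]], "resolution")
  class(out) <- c("TadSet", "data.frame")
  out
}

#' Write TADs as BED3
#'
#' Emits one `chrom<TAB>start<TAB>end` line per TAD, 0-based half-open,
#' sorted by start.
#'
#' @param tads a [tad_set()].
#' @param path output file path.
#' @export
write_tads_bed <- function(tads, path) {
  df <- as.data.frame(tads)[order(tads$start_bp), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d", df$chrom, as.integer(df$start_bp),
                   as.integer(df$end_bp))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read TADs from a BED-like file
#'
#' Accepts 3+ column tab-separated text; extra columns are ignored.
#' Coordinates are 0-based half-open. Starts/ends that are not bin-aligned are
#' snapped outward (`floor(start / resolution)`, `ceiling(end / resolution)`)
#' with a warning.
#'
#' @param path BED file path.
#' @param resolution bin width in bp used to assign bin coordinates.
#' @return a [tad_set()].
#' @export
read_tads_bed <- function(path, resolution) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs >= 3 columns: ", path)
  chrom <- as.character(tab[[1]])
  start <- as.numeric(tab[[2]]); end <- as.numeric(tab[[3]])
  if (any(start >= end)) stop("BED interval with start >= end in ", path)
  if (length(unique(chrom)) > 1L) {
    stop("multiple chromosomes in ", path, "; one chromosome per TadSet")
  }
  if (any(start %% resolution != 0 | end %% resolution != 0)) {
    warning("intervals in ", path, " are not aligned to ", resolution,
            " bp bins; snapping outward")
  }
  tad_set(floor(start / resolution), ceiling(end / resolution),
          chrom = chrom[1], resolution = resolution)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param chrom if given, keep only this chromosome's records.
#' @return a `SignalTrack`: data.frame with `chrom`, `start_bp`, `end_bp`,
#'   `value`, sorted by start.
#' @export
read_bedgraph <- function(path, chrom = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("bedGraph needs 4 columns: ", path)
  df <- data.frame(chrom = as.character(tab[[1]]),
                   start_bp = as.numeric(tab[[2]]),
                   end_bp = as.numeric(tab[[3]]),
                   value = as.numeric(tab[[4]]))
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  if (any(!is.finite(df$value))) stop("non-finite signal value in ", path)
  if (any(df$end_bp <= df$start_bp)) stop("bedGraph interval with end <= start")
  df <- df[order(df$start_bp), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start_bp[-1] < df$end_bp[-nrow(df)])) {
    stop("overlapping bedGraph intervals in ", path)
  }
  rownames(df) <- NULL
  structure(df, class = c("SignalTrack", "data.frame"))
}
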