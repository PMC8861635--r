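#' Bead-chain and contact-set containers
#'
#' A `bead_chain` is an ordered set of 3D bead coordinates representing a
#' coarse-grained chromosome model, one bead per 100 kb of sequence, in units
#' of particle radii. A `ct_contacts` object is the deduplicated, ordered list
#' of intra-chain contacts `(i, j)` between beads, with first neighbors
#' (`|i - j| <= 1`) excluded. Bead indices are 0-based internally; all file
#' output is written 1-based.
#'
#' @param coords numeric matrix with columns x, y, z, one row per bead.
#' @param label chain label (e.g. a chromosome name).
#' @return An object of class `bead_chain`.
#' @export
bead_chain <- function(coords, label = "chain") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) < 2L) stop("a bead chain needs at least 2 beads")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("all bead coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(label = as.character(label)[1L], coords = coords),
            class = "bead_chain")
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf("<bead_chain> '%s': %d beads (100 kb each, %.1f Mb)\n",
              x$label, nrow(x$coords), nrow(x$coords) / 10))
  invisible(x)
}

#' Number of beads in a chain
#' @param chain a `bead_chain`.
#' @export
n_beads <- function(chain) nrow(chain$coords)

#' Construct a contact set
#'
#' Validates, sorts by `(i, j)` and deduplicates a list of bead-index pairs.
#' Contacts between first neighbors are excluded by construction: every
#' contact must satisfy `j >= i + 2`.
#'
#' @param i,j integer vectors of 0-based bead indices, `i < j`.
#' @param n_beads chain length the contacts refer to.
#' @param source provenance: `"spatial_cutoff"`, `"count_threshold"` or
#'   `"synthetic"`.
#' @param param the cutoff/threshold value used, if any.
#' @return An object of class `ct_contacts` with fields `i`, `j`,
#'   `n_beads`, `source`, `param`.
#' @export
ct_contacts <- function(i, j, n_beads,
                        source = c("synthetic", "spatial_cutoff", "count_threshold"),
                        param = NA_real_) {
  source <- match.arg(source)
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j)) stop("i and j must have equal length")
  if (length(i)) {
    swap <- i > j
    if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
    if (any(i < 0L)) stop("bead indices must be non-negative")
    if (any(j >= n_beads)) stop("contact index beyond chain length")
    if (any(j - i < 2L)) stop("first-neighbor contacts (j < i + 2) are not allowed")
    o <- order(i, j)
    i <- i[o]; j <- j[o]
    dup <- duplicated(cbind(i, j))
    i <- i[!dup]; j <- j[!dup]
  }
  structure(list(i = i, j = j, n_beads = as.integer(n_beads),
                 source = source, param = param),
            class = "ct_contacts")
}

#' @export
print.ct_contacts <- function(x, ...) {
  cat(sprintf("<ct_contacts> N = %d contacts on %d beads (source: %s%s)\n",
              length(x$i), x$n_beads, x$source,
              if (is.na(x$param)) "" else sprintf(", param = %g", x$param)))
  invisible(x)
}

#' Number of contacts
#' @param contacts a `ct_contacts` object.
#' @export
n_contacts <- function(contacts) length(contacts$i)

#' Read a bead chain from a coordinate table
#'
#' Accepts whitespace- or tab-separated tables with columns `x y z` or
#' `label x y z`; an optional single header line is skipped automatically.
#' Row k of the file becomes bead k - 1 (0-based).
#'
#' @param path path to the coordinate table.
#' @param label chain label; defaults to the file's label column when present.
#' @return a `bead_chain`.
#' @export
read_chain <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty coordinate file: ", path)
  toks <- strsplit(trimws(lines), "[ \t,]+")
  nc <- lengths(toks)
  if (any(nc < 3L | nc > 4L))
    stop("malformed row at line ", which(nc < 3L | nc > 4L)[1L],
         ": expected 3 or 4 columns")
  has_label <- nc[length(nc)] == 4L
  first_line <- 1L
  num_cols <- function(tk) if (length(tk) == 4L) tk[2:4] else tk
  # a header line is one whose numeric columns do not parse
  if (anyNA(suppressWarnings(as.numeric(num_cols(toks[[1L]])))) &&
      length(toks) > 1L) {
    first_line <- 2L
  }
  rows <- toks[first_line:length(toks)]
  vals <- vapply(rows, function(tk) suppressWarnings(as.numeric(num_cols(tk))),
                 numeric(3))
  bad <- which(apply(is.na(vals), 2L, any))
  if (length(bad))
    stop("parse error at line ", bad[1L] + first_line - 1L,
         ": non-numeric coordinate")
  if (ncol(vals) < 2L) stop("a bead chain needs at least 2 beads")
  if (is.null(label)) {
    label <- if (has_label) rows[[1L]][1L] else "chain"
  }
  bead_chain(t(vals), label = label)
}

#' Write a bead chain as a coordinate table
#'
#' @param chain a `bead_chain`.
#' @param path output file.
#' @param digits significant digits used for coordinates.
#' @export
write_chain <- function(chain, path, digits = 17L) {
  df <- data.frame(label = chain$label,
                   x = formatC(chain$coords[, 1], digits = digits, format = "g"),
                   y = formatC(chain$coords[, 2], digits = digits, format = "g"),
                   z = formatC(chain$coords[, 3], digits = digits, format = "g"))
  write_tsv_plain(df, path, col.names = FALSE)
}

#' Extract contacts from a 3D chain with a spatial cutoff
#'
#' Two beads are in contact when their Euclidean distance is at most `r_c`
#' (in particle radii) and they are not first neighbors along the chain
#' (`j >= i + 2`). The comparison is inclusive, so lattice chains at exact
#' grid distances behave deterministically.
#'
#' @param chain a `bead_chain`.
#' @param r_c spatial cutoff in particle radii; the supported analysis range
#'   in the original study was 0.5--2.0 with 1.0 the default.
#' @return a `ct_contacts` with `source = "spatial_cutoff"`.
#' @export
extract_contacts <- function(chain, r_c = 1.0) {
  if (!is.numeric(r_c) || length(r_c) != 1L || !is.finite(r_c) || r_c <= 0)
    stop("r_c must be a positive number")
  d <- as.matrix(stats::dist(chain$coords))
  n <- nrow(d)
  hit <- which(upper.tri(d) & d <= r_c, arr.ind = TRUE)
  if (nrow(hit)) {
    keep <- hit[, 2L] - hit[, 1L] >= 2L
    hit <- hit[keep, , drop = FALSE]
  }
  ct_contacts(hit[, 1L] - 1L, hit[, 2L] - 1L, n_beads = n,
              source = "spatial_cutoff", param = r_c)
}

#' Contacts from a Hi-C count matrix
#'
#' Bin pairs with a count at or above `threshold` become contacts; adjacent
#' and identical bins are excluded (first-neighbor rule). Dense input must be
#' square; an upper-triangular or asymmetric matrix is symmetrized by taking
#' the elementwise maximum of mirror entries before validation. Sparse COO
#' input is a 3-column table `bin_i bin_j count` of 1-based bin indices.
#' When downstream analyses need genomic coordinates, the midpoint of each
#' bin (`(bin + 0.5) * bin_bp`) is the contact-site coordinate; see
#' [contact_midpoints()].
#'
#' @param x square count matrix, or a 3-column data frame/matrix of COO
#'   triplets (1-based bins).
#' @param threshold minimum count for a pair to be called a contact
#'   (default 250, the value used for the headline population analysis).
#' @param bin_bp genomic bin size in bp (metadata; default 1e5).
#' @param n_bins number of bins, required for COO input when it cannot be
#'   inferred from the largest index.
#' @return a `ct_contacts` with `source = "count_threshold"` and attribute
#'   `bin_bp`.
#' @export
contacts_from_hic <- function(x, threshold = 250, bin_bp = 1e5, n_bins = NULL) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (is.data.frame(x) || (is.matrix(x) && ncol(x) == 3L && nrow(x) != 3L)) {
    coo <- as.matrix(x)
    if (ncol(coo) != 3L) stop("COO input needs 3 columns: bin_i bin_j count")
    if (any(coo[, 3L] < 0)) stop("counts must be non-negative")
    nb <- n_bins %||% max(coo[, 1:2])
    m <- matrix(0, nb, nb)
    # symmetrize by max of mirror entries
    idx <- cbind(coo[, 1L], coo[, 2L])
    m[idx] <- pmax(m[idx], coo[, 3L])
    idx2 <- idx[, 2:1, drop = FALSE]
    m[idx2] <- pmax(m[idx2], coo[, 3L])
    x <- m
  } else {
    x <- as.matrix(x)
    if (nrow(x) != ncol(x)) stop("Hi-C count matrix must be square")
    if (any(x < 0)) stop("counts must be non-negative")
    x <- pmax(x, t(x))  # tolerate stored upper triangles
  }
  hit <- which(upper.tri(x) & x >= threshold, arr.ind = TRUE)
  if (nrow(hit)) hit <- hit[hit[, 2L] - hit[, 1L] >= 2L, , drop = FALSE]
  out <- ct_contacts(hit[, 1L] - 1L, hit[, 2L] - 1L, n_beads = nrow(x),
                     source = "count_threshold", param = threshold)
  attr(out, "bin_bp") <- bin_bp
  out
}

#' Genomic midpoints of contact sites
#'
#' @param contacts a `ct_contacts`.
#' @param bin_bp bin (bead) size in bp; defaults to the `bin_bp` attribute
#'   when present, else 1e5.
#' @return two-column matrix of midpoint coordinates (bp) for the left and
#'   right site of each contact.
#' @export
contact_midpoints <- function(contacts, bin_bp = NULL) {
  bin_bp <- bin_bp %||% attr(contacts, "bin_bp") %||% 1e5
  cbind(left = (contacts$i + 0.5) * bin_bp,
        right = (contacts$j + 0.5) * bin_bp)
}

#' Read a dense Hi-C matrix from a TSV file
#' @param path path to a whitespace-separated numeric matrix.
#' @export
read_hic_dense <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Read sparse COO Hi-C triplets (`bin_i bin_j count`, 1-based)
#' @param path path to the triplet file.
#' @export
read_hic_coo <- function(path) {
  df <- utils::read.table(path, header = FALSE)
  if (ncol(df) != 3L) stop("COO file needs 3 columns: bin_i bin_j count")
  names(df) <- c("bin_i", "bin_j", "count")
  df
}

#' Read a BED-like expression track
#'
#' Four tab-separated columns: chrom, start, end, abundance; 0-based
#' half-open coordinates. The track is sorted on read; overlapping bins are
#' rejected.
#'
#' @param path path to the track file.
#' @return an `expression_track` data frame (chrom, start, end, abundance).
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "abundance"))
  expression_track(df)
}

#' Construct/validate an expression track
#' @param df data frame with columns chrom, start, end, abundance.
#' @export
expression_track <- function(df) {
  need <- c("chrom", "start", "end", "abundance")
  if (!all(need %in% names(df))) stop("track needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$chrom, df$start), need, drop = FALSE]
  if (any(df$end <= df$start)) stop("bins must have end > start")
  if (any(df$abundance < 0)) stop("abundance must be non-negative")
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1L) {
      bad <- which(sub$start[-1L] < sub$end[-nrow(sub)])
      if (length(bad))
        stop(sprintf("overlapping bins on %s: [%d,%d) and [%d,%d)",
                     ch, sub$start[bad[1L]], sub$end[bad[1L]],
                     sub$start[bad[1L] + 1L], sub$end[bad[1L] + 1L]))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("expression_track", "data.frame")
  df
}

#' Write contacts as TSV (1-based indices)
#' @param contacts a `ct_contacts`.
#' @param path output file.
#' @param chrom chromosome label written in the first column.
#' @export
write_contacts_tsv <- function(contacts, path, chrom = "chain") {
  df <- data.frame(chrom = chrom, i = contacts$i + 1L, j = contacts$j + 1L)
  write_tsv_plain(df, path)
}

#' Read contacts from TSV (chrom, i, j; 1-based indices)
#' @param path contacts file.
#' @param n_beads chain length; inferred from the largest index when omitted.
#' @export
read_contacts_tsv <- function(path, n_beads = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  nb <- n_beads %||% (max(df$j))
  ct_contacts(df$i - 1L, df$j - 1L, n_beads = nb, source = "synthetic")
}
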