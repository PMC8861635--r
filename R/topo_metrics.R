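#' 1D topological traces
#'
#' A `ct_trace` is a data frame with a strictly increasing `position` column
#' (bead index or bp, see the `unit` attribute) and a non-negative `value`
#' column, carrying a topological quantity along the chain.
#'
#' @param position numeric positions (strictly increasing).
#' @param value numeric values, same length.
#' @param kind what the values measure, e.g. `"per_site_entanglement"`.
#' @param unit `"bead"` or `"bp"`.
#' @param bead_bp bead size in bp (default 1e5 = 100 kb).
#' @export
ct_trace <- function(position, value, kind = "trace", unit = "bead",
                     bead_bp = 1e5) {
  if (length(position) != length(value)) stop("position/value length mismatch")
  if (length(position) > 1L && any(diff(position) <= 0))
    stop("positions must be strictly increasing")
  structure(data.frame(position = position, value = value),
            class = c("ct_trace", "data.frame"),
            kind = kind, unit = unit, bead_bp = bead_bp)
}

#' Entangled fraction of a topology matrix
#'
#' The share of entangled unordered contact pairs among all `N(N-1)/2`
#' pairs. Entangled means parallel (P or P_inv) or cross (X) by default;
#' concerted-parallel relations can be included for sensitivity analysis.
#'
#' @param m a `topology_matrix` with `N >= 2` contacts.
#' @param entangled character vector of relation names counted as entangled.
#' @return a fraction in \[0, 1\].
#' @export
entangled_fraction <- function(m, entangled = entangled_set()) {
  stopifnot(inherits(m, "topology_matrix"))
  n <- nrow(m)
  if (n < 2L) stop("entangled fraction is undefined for fewer than 2 contacts")
  up <- m[upper.tri(m)]
  sum(up %in% codes_of(entangled)) / (n * (n - 1L) / 2L)
}

#' Per-contact entanglement counts
#'
#' For each contact (matrix row), the number of entangled relations it
#' experiences, i.e. the number of other contacts with which it is in a
#' parallel or cross relation.
#'
#' @inheritParams entangled_fraction
#' @return integer vector of length N.
#' @export
contact_entanglement <- function(m, entangled = entangled_set()) {
  stopifnot(inherits(m, "topology_matrix"))
  rowSums(matrix(m %in% codes_of(entangled), nrow(m)))
}

#' Project contact entanglement onto chain positions
#'
#' Sums, for every bead, the row entanglement counts of all contacts having
#' that bead as either endpoint, yielding a 1D trace of the overall
#' entanglement experienced by each 100 kb contact site. Beads without
#' contacts get 0. Both endpoints of a contact are credited.
#'
#' @param contacts a [ct_contacts].
#' @param row_counts per-contact entanglement from [contact_entanglement()]
#'   computed on the same contact set.
#' @return a [ct_trace] over beads `0 .. n_beads - 1`.
#' @export
site_entanglement_trace <- function(contacts, row_counts) {
  if (length(row_counts) != n_contacts(contacts))
    stop("row_counts must have one entry per contact")
  v <- numeric(contacts$n_beads)
  ends <- c(contacts$i, contacts$j) + 1L
  w <- rep(row_counts, 2L)
  for (k in seq_along(ends)) v[ends[k]] <- v[ends[k]] + w[k]
  ct_trace(0:(contacts$n_beads - 1L), v, kind = "per_site_entanglement")
}

#' Entanglement-annotated contact map
#'
#' Renders the per-contact entanglement counts onto an `n_beads x n_beads`
#' contact-map matrix: cells `(i, j)` and `(j, i)` of each contact carry its
#' row count. This is the heatmap projection of [contact_entanglement()],
#' not a separate computation.
#'
#' @inheritParams site_entanglement_trace
#' @return numeric matrix `n_beads x n_beads`.
#' @export
entanglement_contact_map <- function(contacts, row_counts) {
  n <- contacts$n_beads
  m <- matrix(0, n, n)
  m[cbind(contacts$i + 1L, contacts$j + 1L)] <- row_counts
  m[cbind(contacts$j + 1L, contacts$i + 1L)] <- row_counts
  m
}

#' Bin a trace into fixed genomic windows
#'
#' Values are summed per bin of `bin_bp` base pairs; a bead belongs to the
#' bin containing its start coordinate. The full chain extent is covered, so
#' trailing empty bins are kept as zeros.
#'
#' @param trace a [ct_trace] with bead-unit positions.
#' @param bin_bp bin size in bp; must be a multiple of the bead size
#'   (default 1 Mb bins of 100 kb beads).
#' @return a [ct_trace] with `unit = "bp"`, positions at bin starts, and the
#'   bin size in `attr(, "bin_bp")`.
#' @export
bin_trace <- function(trace, bin_bp = 1e6) {
  bead_bp <- attr(trace, "bead_bp") %||% 1e5
  if (bin_bp < bead_bp) stop("bin size smaller than bead size")
  if (bin_bp %% bead_bp != 0) stop("bin size must be a multiple of the bead size")
  pos_bp <- trace$position * bead_bp
  bin <- floor(pos_bp / bin_bp)
  nbin <- max(bin) + 1L
  v <- numeric(nbin)
  agg <- tapply(trace$value, bin, sum)
  v[as.integer(names(agg)) + 1L] <- agg
  out <- ct_trace((0:(nbin - 1L)) * bin_bp, v, kind = attr(trace, "kind"),
                  unit = "bp", bead_bp = bead_bp)
  attr(out, "bin_bp") <- bin_bp
  out
}

#' Bin per-contact entanglement along the sequence
#'
#' Contact-level binning: each contact's entanglement count is credited to
#' the bin of its *first* (smaller) contact site along the sequence.
#'
#' @inheritParams site_entanglement_trace
#' @param bin_bp bin size in bp (default 1 Mb).
#' @param bead_bp bead size in bp.
#' @return a [ct_trace] of per-bin sums (`unit = "bp"`).
#' @export
entanglement_by_bin <- function(contacts, row_counts, bin_bp = 1e6,
                                bead_bp = 1e5) {
  if (length(row_counts) != n_contacts(contacts))
    stop("row_counts must have one entry per contact")
  nbin <- ceiling(contacts$n_beads * bead_bp / bin_bp)
  v <- numeric(nbin)
  bin <- floor(contacts$i * bead_bp / bin_bp) + 1L
  for (k in seq_along(bin)) v[bin[k]] <- v[bin[k]] + row_counts[k]
  out <- ct_trace((0:(nbin - 1L)) * bin_bp, v, kind = "binned_entanglement",
                  unit = "bp", bead_bp = bead_bp)
  attr(out, "bin_bp") <- bin_bp
  out
}

#' Correlate a binned entanglement trace with gene expression
#'
#' Gene abundances are summed into the trace's bins by gene midpoint;
#' abundances below `abundance_floor` (per bin) are set to zero; the two
#' binned signals are then compared by Pearson correlation with a two-sided
#' p value.
#'
#' @param binned a binned [ct_trace] (from [bin_trace()] or
#'   [entanglement_by_bin()]) carrying a `bin_bp` attribute.
#' @param track an [expression_track].
#' @param abundance_floor per-bin abundance below which expression is zeroed
#'   (default 50 per Mb, the value used in the reference analysis).
#' @return list with `r`, `p`, `n_bins`, and the two binned vectors.
#' @export
correlate_with_expression <- function(binned, track, abundance_floor = 50) {
  bin_bp <- attr(binned, "bin_bp")
  if (is.null(bin_bp)) stop("binned trace must carry a bin_bp attribute")
  nbin <- nrow(binned)
  mid <- (track$start + track$end) / 2
  bin <- floor(mid / bin_bp) + 1L
  ab <- numeric(nbin)
  keep <- bin >= 1L & bin <= nbin
  agg <- tapply(track$abundance[keep], bin[keep], sum)
  ab[as.integer(names(agg))] <- agg
  ab[ab < abundance_floor] <- 0
  if (nbin < 3L) stop("need at least 3 common bins")
  if (stats::sd(ab) == 0 || stats::sd(binned$value) == 0)
    stop("constant signal: correlation undefined")
  ct <- stats::cor.test(binned$value, ab, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = nbin,
       entanglement = binned$value, abundance = ab)
}

#' Radius of gyration of a bead chain
#'
#' Root-mean-square distance of the beads from their centroid, in particle
#' radii.
#'
#' @param chain a [bead_chain].
#' @export
radius_of_gyration <- function(chain) {
  x <- chain$coords
  ctr <- colMeans(x)
  sqrt(mean(rowSums((x - matrix(ctr, nrow(x), 3L, byrow = TRUE))^2)))
}

#' Write a trace as TSV
#' @param trace a [ct_trace].
#' @param path output file.
#' @export
write_trace_tsv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bb <- attr(trace, "bin_bp")
  if (!is.null(bb)) writeLines(sprintf("# bin_bp=%g", bb), con)
  writeLines(sprintf("# unit=%s kind=%s", attr(trace, "unit"),
                     attr(trace, "kind")), con)
  utils::write.table(as.data.frame(trace), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
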