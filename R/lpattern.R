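#' L-pattern lengths of a topology matrix
#'
#' An L-pattern is the elongated parallel-dominated feature an enveloping
#' contact (a *turn*) leaves along the topology-matrix diagonal, possibly
#' striped by cross contacts. Its length is obtained by counting, for each
#' matrix line, the entangled relations from the diagonal rightward; each
#' entangled pair is thereby attributed to its earlier contact, so the
#' lengths sum to the number of entangled unordered pairs.
#'
#' @param m a `topology_matrix`.
#' @param entangled entangled relation names (default [entangled_set()]).
#' @return integer vector of length N: per-contact L-pattern length.
#' @export
lpattern_lengths <- function(m, entangled = entangled_set()) {
  stopifnot(inherits(m, "topology_matrix"))
  codes <- codes_of(entangled)
  ent <- matrix(m %in% codes, nrow(m))
  ent[!upper.tri(ent)] <- FALSE
  as.integer(rowSums(ent))
}

#' Split a topology matrix into parallel and cross components
#'
#' @param m a `topology_matrix`.
#' @return list of two 0/1 matrices, `parallel` (P and P_inv cells) and
#'   `cross` (X cells); their union equals the entangled binarization.
#' @export
split_components <- function(m) {
  stopifnot(inherits(m, "topology_matrix"))
  list(parallel = matrix(as.integer(m %in% codes_of(c("P", "P_inv"))), nrow(m)),
       cross = matrix(as.integer(m == ct_codes[["X"]]), nrow(m)))
}

#' Turn groups: nested L-patterns of the matrix
#'
#' A *turn* is a contact that strictly envelops (is in inverse-parallel
#' relation over) at least `min_enveloped` other contacts and is not itself
#' a cross stripe -- a contact in cross relation with an earlier turn
#' candidate, which in the L-loop motif arises when the growing loop touches
#' another chain region and cuts through the pattern rather than extending
#' it. Turns are grouped into nested L-patterns: walking the turns in
#' containment order, a group continues while the outer turn directly
#' envelops the next one with no non-turn contact (a *pocket*) sitting
#' inside the outer turn but disjoint from the next; a pocket in between
#' closes the group.
#'
#' @param m a `topology_matrix`.
#' @param min_enveloped minimum number of strictly enveloped contacts for a
#'   contact to qualify as a turn (default 1).
#' @return list of integer vectors of 1-based contact indices, outermost
#'   group first; the number of groups is the nested L-pattern count.
#' @export
turn_groups <- function(m, min_enveloped = 1L) {
  stopifnot(inherits(m, "topology_matrix"))
  contacts <- attr(m, "contacts")
  n <- nrow(m)
  # how many contacts each one strictly envelops
  envelops <- rowSums(matrix(m == ct_codes[["P_inv"]], n))
  cand <- which(envelops >= min_enveloped)
  if (!length(cand)) return(list())
  # drop cross stripes: X relation with a lower-index candidate
  is_stripe <- vapply(cand, function(c1) {
    earlier <- cand[cand < c1]
    length(earlier) && any(m[c1, earlier] == ct_codes[["X"]])
  }, logical(1))
  turns <- cand[!is_stripe]
  if (!length(turns)) return(list())
  # containment order: by left site ascending, right site descending
  ord <- order(contacts$i[turns], -contacts$j[turns])
  turns <- turns[ord]
  nonturn <- setdiff(seq_len(n), turns)
  groups <- list(turns[1L])
  for (k in seq_along(turns)[-1L]) {
    t_prev <- turns[k - 1L]; t_next <- turns[k]
    enveloped <- m[t_next, t_prev] == ct_codes[["P"]]
    pocket_between <- FALSE
    if (enveloped && length(nonturn)) {
      inside_prev <- m[nonturn, t_prev] == ct_codes[["P"]]
      disjoint_next <- m[nonturn, t_next] %in%
        c(ct_codes[["S"]], ct_codes[["CS"]])
      pocket_between <- any(inside_prev & disjoint_next)
    }
    if (enveloped && !pocket_between) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], t_next)
    } else {
      groups[[length(groups) + 1L]] <- t_next
    }
  }
  groups
}

#' Segment barcode of L-pattern content
#'
#' The chain is split into `n_segments` segments of equal bead count
#' (remainder beads go to the last segment); each contact's L-pattern length
#' is credited to the segment containing its smaller (first) endpoint,
#' mirroring the sequence-binning rule of the 1 Mb projection.
#'
#' @param lengths per-contact L-pattern lengths from [lpattern_lengths()].
#' @param contacts the originating [ct_contacts].
#' @param n_segments number of segments (default 4; 8 also commonly used).
#' @return numeric vector of per-segment sums.
#' @export
segment_barcode <- function(lengths, contacts, n_segments = 4L) {
  if (n_segments < 2L) stop("need at least 2 segments")
  nb <- contacts$n_beads
  if (n_segments > nb) stop("more segments than beads")
  if (length(lengths) != n_contacts(contacts))
    stop("lengths must have one entry per contact")
  seg_len <- nb %/% n_segments
  seg <- pmin(contacts$i %/% seg_len + 1L, n_segments)  # remainder -> last
  out <- numeric(n_segments)
  for (k in seq_along(seg)) out[seg[k]] <- out[seg[k]] + lengths[k]
  out
}

#' Position of the maximal barcode segment
#'
#' @param barcode per-segment sums from [segment_barcode()].
#' @return 1-based index of the maximal segment (ties resolve to the
#'   smallest index). An all-zero barcode returns `NA` with attribute
#'   `no_lloops = TRUE` and a warning.
#' @export
maxima_position <- function(barcode) {
  if (!length(barcode)) stop("empty barcode")
  if (all(barcode == 0)) {
    warning("no L-loops: all-zero barcode")
    out <- NA_integer_
    attr(out, "no_lloops") <- TRUE
    return(out)
  }
  which.max(barcode)
}

#' Split L-pattern lengths at their median
#'
#' Zero lengths (contacts heading no L-pattern) are excluded; the median is
#' computed over the nonzero lengths and the set is split into below-median
#' and at-or-above-median halves (the median element itself, when attained,
#' goes to the upper half).
#'
#' @param lengths L-pattern lengths (possibly pooled across chromosomes).
#' @return list with `below`, `above`, `median`, and summary statistics of
#'   each half.
#' @export
quantile_split <- function(lengths) {
  nz <- lengths[lengths > 0]
  if (length(nz) < 2L) stop("need at least 2 nonzero lengths")
  med <- stats::median(nz)
  below <- nz[nz < med]
  above <- nz[nz >= med]
  list(below = sort(below), above = sort(above), median = med,
       summary = list(below = summary(below), above = summary(above)))
}

#' Write an L-pattern profile (contact index vs length) as TSV
#' @param lengths from [lpattern_lengths()].
#' @param path output file.
#' @export
write_lprofile_tsv <- function(lengths, path) {
  write_tsv_plain(data.frame(contact = seq_along(lengths),
                             lpattern_length = lengths), path)
}
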