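#' Circuit-topology relation codes
#'
#' Integer codes used throughout the package for the pairwise relation of two
#' intra-chain contacts `A = (i, j)` and `B = (r, s)` (closed integer
#' intervals of bead indices):
#'
#' * `S`  (series): the intervals are disjoint.
#' * `P`  (parallel): `[i, j]` lies strictly inside the open interval `(r, s)`.
#' * `P_inv`: the inverse view, `B` strictly inside `A`.
#' * `X`  (cross): the intervals overlap without containment or a shared site.
#' * `CS` (concerted series): the intervals share exactly one contact site.
#' * `CP` / `CP_inv` (concerted parallel): containment with a shared endpoint.
#' * `NONE`: the excluded matrix diagonal.
#'
#' Concerted relations take priority: whenever a contact site is shared, the
#' pair is CS or CP/CP_inv, never S/P/X. This makes the classification total
#' and exclusive.
#'
#' @format named integer vector mapping code names to the integers stored in
#'   topology matrices (`NONE = 0, S = 1, P = 2, P_inv = 3, X = 4, CS = 5,
#'   CP = 6, CP_inv = 7`).
#' @export
ct_codes <- c(NONE = 0L, S = 1L, P = 2L, P_inv = 3L, X = 4L,
              CS = 5L, CP = 6L, CP_inv = 7L)

#' Default entangled relation set
#'
#' Parallel and cross relations are grouped as *entangled*; series is
#' unentangled. Concerted relations form their own subgroup and are excluded
#' by default, but can be added for sensitivity analysis.
#'
#' @param include_concerted also count CP/CP_inv as entangled.
#' @return character vector of relation code names.
#' @export
entangled_set <- function(include_concerted = FALSE) {
  base <- c("P", "P_inv", "X")
  if (include_concerted) c(base, "CP", "CP_inv") else base
}

# vectorized classifier on parallel endpoint vectors; returns integer codes
# for the relation of contact a = (ia, ja) with respect to b = (ib, jb)
classify_codes <- function(ia, ja, ib, jb) {
  dup <- ia == ib & ja == jb
  cs  <- ia == jb | ja == ib
  cp  <- (ia == ib & ja < jb) | (ja == jb & ia > ib)
  cpi <- (ia == ib & ja > jb) | (ja == jb & ia < ib)
  s   <- ja < ib | jb < ia
  p   <- ia > ib & ja < jb
  pin <- ia < ib & ja > jb
  out <- ifelse(dup, ct_codes[["NONE"]],
         ifelse(cs,  ct_codes[["CS"]],
         ifelse(cp,  ct_codes[["CP"]],
         ifelse(cpi, ct_codes[["CP_inv"]],
         ifelse(s,   ct_codes[["S"]],
         ifelse(p,   ct_codes[["P"]],
         ifelse(pin, ct_codes[["P_inv"]], ct_codes[["X"]])))))))
  storage.mode(out) <- "integer"
  out
}

#' Classify the circuit-topology relation of two contacts
#'
#' Returns the relation of contact `a` *with respect to* contact `b`:
#' `"P"` means `a` is enveloped by `b`, `"P_inv"` that `a` envelops `b`,
#' and likewise for `CP`/`CP_inv`. `S`, `X` and `CS` are symmetric.
#'
#' @param a,b contacts as length-2 integer vectors `c(i, j)` with `j >= i + 2`.
#' @return a single relation code name (see [ct_codes]).
#' @examples
#' classify_pair(c(1, 5), c(7, 9))  # "S"
#' classify_pair(c(3, 7), c(1, 9))  # "P"
#' classify_pair(c(1, 5), c(3, 9))  # "X"
#' classify_pair(c(1, 5), c(5, 9))  # "CS"
#' @export
classify_pair <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != 2L || length(b) != 2L) stop("contacts are length-2 vectors")
  if (a[1L] >= a[2L] || b[1L] >= b[2L]) stop("contacts must satisfy i < j")
  if (a[1L] == b[1L] && a[2L] == b[2L]) stop("duplicate contact")
  code <- classify_codes(a[1L], a[2L], b[1L], b[2L])
  names(ct_codes)[match(code, ct_codes)]
}

#' Build the topology matrix of a contact set
#'
#' The topology matrix is N x N for N contacts; cell `[a, b]` holds the
#' relation of contact `a` with respect to contact `b`, and the diagonal is
#' excluded (`NONE`). Contacts are indexed in `(i, j)`-sorted order, i.e. as
#' their left sites appear scanning the chain left to right.
#'
#' @param contacts a [ct_contacts] object with at least one contact.
#' @return integer matrix of class `topology_matrix` with the relation codes
#'   of [ct_codes]; the originating contact set is kept in
#'   `attr(, "contacts")`.
#' @export
build_topology_matrix <- function(contacts) {
  stopifnot(inherits(contacts, "ct_contacts"))
  n <- n_contacts(contacts)
  if (n < 1L) stop("no contacts")
  ia <- matrix(contacts$i, n, n); ja <- matrix(contacts$j, n, n)
  ib <- t(ia); jb <- t(ja)
  m <- matrix(classify_codes(ia, ja, ib, jb), n, n)
  structure(m, class = "topology_matrix", contacts = contacts)
}

#' @export
print.topology_matrix <- function(x, ...) {
  n <- nrow(x)
  cc <- relation_counts(x)
  cat(sprintf("<topology_matrix> %d x %d (%d contact pairs)\n", n, n,
              n * (n - 1L) / 2L))
  cat("  pair counts:", paste(names(cc), cc, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Count relation types over unordered contact pairs
#'
#' P/P_inv collapse to a single "parallel pair" count and CP/CP_inv to one
#' "concerted-parallel pair" count, so the counts sum to `N(N-1)/2`.
#'
#' @param m a `topology_matrix`.
#' @return named integer vector with counts for S, P, X, CS, CP.
#' @export
relation_counts <- function(m) {
  stopifnot(inherits(m, "topology_matrix"))
  up <- m[upper.tri(m)]
  c(S  = sum(up == ct_codes[["S"]]),
    P  = sum(up == ct_codes[["P"]] | up == ct_codes[["P_inv"]]),
    X  = sum(up == ct_codes[["X"]]),
    CS = sum(up == ct_codes[["CS"]]),
    CP = sum(up == ct_codes[["CP"]] | up == ct_codes[["CP_inv"]]))
}

# integer codes for a set of relation names
codes_of <- function(names) unname(ct_codes[names])

#' Write a topology matrix as TSV of integer codes
#' @param m a `topology_matrix`.
#' @param path output file.
#' @export
write_topology_tsv <- function(m, path) {
  utils::write.table(unclass(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a topology matrix as an 8-bit grayscale TIFF
#'
#' Pixel values are the integer relation codes of [ct_codes] (0--7), stored
#' in an 8-bit single-channel TIFF.
#'
#' @param m a `topology_matrix` or any integer matrix of codes.
#' @param path output file.
#' @export
write_topology_tiff <- function(m, path) {
  tiff::writeTIFF(unclass(m) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit TIFF back into an integer code matrix
#' @param path TIFF file written by [write_topology_tiff()] (or any 8-bit
#'   grayscale matrix; values are rescaled from \[0, 1\] to 0--255 and rounded).
#' @export
read_code_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}
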