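# Independent relation classifier built on literal set algebra over the
# enumerated bead sets of the two closed intervals. Deliberately shares no
# code with classify_pair(): conditions are evaluated on explicit sets.
oracle_classify <- function(a, b) {
  si <- seq(a[1], a[2]); sr <- seq(b[1], b[2])
  inter <- intersect(si, sr)
  if (setequal(si, sr)) stop("duplicate contact")
  if (length(inter) == 1 && (inter == a[1] || inter == a[2])) return("CS")
  if (all(si %in% sr) && (a[1] == b[1] || a[2] == b[2])) return("CP")
  if (all(sr %in% si) && (a[1] == b[1] || a[2] == b[2])) return("CP_inv")
  if (length(inter) == 0) return("S")
  open_b <- setdiff(sr, c(b[1], b[2]))
  if (all(si %in% open_b)) return("P")
  open_a <- setdiff(si, c(a[1], a[2]))
  if (all(sr %in% open_a)) return("P_inv")
  "X"
}

# all admissible contacts (j >= i + 2) with endpoints in 0..max_bead
all_admissible_contacts <- function(max_bead) {
  out <- list()
  for (i in 0:(max_bead - 2)) for (j in (i + 2):max_bead)
    out[[length(out) + 1L]] <- c(i, j)
  out
}

# one random admissible contact on a chain of n beads
rand_contact <- function(n) {
  i <- sample.int(n - 2L, 1L) - 1L
  js <- (i + 2L):(n - 1L)
  c(i, js[sample.int(length(js), 1L)])
}
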