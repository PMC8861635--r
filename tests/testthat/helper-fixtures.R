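# Structured contact sets rich in nested L-loops: blocks of two turns plus
# inward-marching pockets laid in series along the chain, with seed-jittered
# spans. Used as the ordered counterpart of the lattice random-chain null.
structured_lloops <- function(n_target, n_beads = 150L, seed = 1) {
  set.seed(seed)
  i <- integer(); j <- integer()
  block_start <- 0L
  while (length(i) < n_target) {
    L <- sample(20:30, 1)
    if (block_start + L >= n_beads) { block_start <- 0L; L <- 25L }
    o <- block_start
    i <- c(i, o, o + 1L); j <- c(j, o + L, o + L - 1L)   # turns
    pos <- o + 2L
    while (pos + 4L < o + L - 2L && length(i) < n_target) {
      p <- sample(2:4, 1)                                 # pocket
      i <- c(i, pos); j <- c(j, pos + p + 1L)
      pos <- pos + p + 2L
    }
    block_start <- block_start + L + 2L
  }
  ct_contacts(i[seq_len(n_target)], j[seq_len(n_target)], n_beads = n_beads)
}
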