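#' Constrained lattice random chain (null model)
#'
#' Random walk on the integer grid inside a box, one step per bead
#' (grid step = one particle = 100 kb). Each move is one of the at most six
#' axis moves that stay inside the box and do not reverse the previous step
#' (the chain may not fold onto itself in two steps); the start site is
#' uniform in the box. If every move is blocked (possible only in degenerate
#' boxes), the walk restarts from a new start point, up to `max_restarts`
#' times.
#'
#' @param n_steps number of beads in the chain (>= 2).
#' @param box integer vector of 3 wall lengths in particles (all >= 2);
#'   positions along axis k range over `0 .. box[k] - 1`. Defaults should be
#'   matched to the per-axis extent of a reference chromosome when used as a
#'   null model (see [box_from_chain()]).
#' @param seed RNG seed; the surrounding RNG state is preserved.
#' @param max_restarts restart budget before giving up.
#' @return a [bead_chain] on lattice coordinates.
#' @export
random_chain <- function(n_steps, box = c(10L, 10L, 10L), seed = NULL,
                         max_restarts = 100L) {
  if (n_steps < 2L) stop("need at least 2 beads")
  box <- as.integer(box)
  if (length(box) != 3L || any(box < 2L)) stop("box walls must be 3 integers >= 2")
  moves <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  with_preserved_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      pos <- matrix(NA_real_, n_steps, 3L)
      pos[1L, ] <- vapply(box, function(L) sample.int(L, 1L) - 1L, numeric(1))
      ok <- TRUE
      for (t in 2:n_steps) {
        cand <- sweep(moves, 2L, pos[t - 1L, ], "+")
        in_box <- cand[, 1L] >= 0 & cand[, 1L] < box[1L] &
                  cand[, 2L] >= 0 & cand[, 2L] < box[2L] &
                  cand[, 3L] >= 0 & cand[, 3L] < box[3L]
        if (t > 2L) {
          reverses <- rowSums(abs(sweep(cand, 2L, pos[t - 2L, ], "-"))) == 0
          in_box <- in_box & !reverses
        }
        opts <- which(in_box)
        if (!length(opts)) { ok <- FALSE; break }
        pick <- opts[sample.int(length(opts), 1L)]
        pos[t, ] <- cand[pick, ]
      }
      if (ok) return(bead_chain(pos, label = "random_chain"))
    }
    stop("random walk dead-ended in ", max_restarts, " restarts")
  })
}

#' Box dimensions matched to a reference chain
#'
#' The per-axis extent of the chain, in particles, defines the wall lengths
#' of the confining box for the random-chain null model.
#'
#' @param chain a [bead_chain].
#' @return integer vector of 3 wall lengths (each at least 2).
#' @export
box_from_chain <- function(chain) {
  ext <- apply(chain$coords, 2L, function(v) diff(range(v)))
  pmax(2L, as.integer(ceiling(ext)) + 1L)
}

#' Contact set of trefoils in series
#'
#' `k` disjoint contact triples, each two concerted-series contacts
#' enveloped by a concerted-parallel contact -- the trefoil configuration
#' that closes a triangle in the contact network. Triple `t` (0-based) is
#' `{(st, st+2), (st+2, st+4), (st, st+4)}` with stride `s = 6`, which
#' keeps consecutive triples disjoint and respects the first-neighbor
#' exclusion. A network of such trefoils in series has average clustering
#' coefficient exactly 1.
#'
#' @param k number of trefoils (>= 1).
#' @param stride spacing between triple origins in beads (>= 6 keeps the
#'   triples disjoint).
#' @return a [ct_contacts] with `3k` contacts on `6(k-1) + 5` beads.
#' @export
trefoil_series <- function(k, stride = 6L) {
  if (k < 1L) stop("k must be at least 1")
  if (stride < 6L) stop("stride < 6 makes consecutive trefoils share sites")
  t <- rep(stride * (seq_len(k) - 1L), each = 3L)
  i <- t + c(0L, 2L, 0L)
  j <- t + c(2L, 4L, 4L)
  ct_contacts(i, j, n_beads = stride * (k - 1L) + 5L, source = "synthetic")
}

#' The canonical nine-contact L-loop fixture
#'
#' A hand-built contact set on a 124-bead chain realizing the canonical
#' L-loop motif: two outer turns (contacts 1, 2) enveloping everything,
#' three turn + pocket repeats (pockets are contacts 3, 6 and 9), and one
#' cross contact (contact 8) striping the inner pattern. The outer L-pattern
#' has length 8 (contact 1 envelops all eight others), the matrix holds
#' three nested L-patterns (turn groups {1,2}, {4,5}, {7}), and the
#' entangled fraction is 27/36. The exact site coordinates are a fixture
#' choice; the asserted properties are coordinate-independent.
#'
#' @return a [ct_contacts] of 9 contacts on 124 beads.
#' @export
lloop_fixture <- function() {
  i <- c(0L, 1L, 2L, 14L, 15L, 16L, 28L, 50L, 60L)
  j <- c(120L, 119L, 12L, 110L, 109L, 26L, 100L, 112L, 70L)
  ct_contacts(i, j, n_beads = 124L, source = "synthetic")
}

#' Periodic synthetic trace
#'
#' Sinusoid plus seeded Gaussian noise, clipped to non-negative values; used
#' to exercise the smoothing / peak-detection / spacing pipeline with a
#' planted periodicity.
#'
#' @param period_beads period in beads (>= 10).
#' @param amplitude sinusoid amplitude.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n trace length in beads (>= 3 periods).
#' @param seed RNG seed.
#' @param baseline constant offset keeping the clipped signal sinusoidal.
#' @return a [ct_trace] over beads `0 .. n - 1`.
#' @export
periodic_trace <- function(period_beads, amplitude, noise_sd, n, seed = NULL,
                           baseline = 0.5) {
  if (period_beads < 10) stop("period must be at least 10 beads")
  if (n < 3 * period_beads) stop("trace must cover at least 3 periods")
  with_preserved_seed(seed, {
    t <- 0:(n - 1L)
    v <- baseline + amplitude * sin(2 * pi * t / period_beads) +
      stats::rnorm(n, 0, noise_sd)
    ct_trace(t, pmax(v, 0), kind = "periodic")
  })
}

#' Expression track with a controlled correlation to a trace
#'
#' Per-bin abundances are a `rho`-weighted Gaussian mixture of the
#' standardized trace and seeded noise, affinely mapped to non-negative
#' counts. With `rho = 1` the track is an exact affine transform of the
#' trace.
#'
#' @param trace a [ct_trace]; one expression bin is generated per element.
#' @param rho target Pearson correlation, `|rho| <= 1`.
#' @param seed RNG seed.
#' @param bin_bp bin width in bp (default 1 Mb).
#' @param base,scale affine map: `abundance = base + scale * mixture`.
#' @param chrom chromosome label.
#' @return an [expression_track] with one bin per trace element.
#' @export
synthetic_expression <- function(trace, rho, seed = NULL, bin_bp = 1e6,
                                 base = 600, scale = 100, chrom = "chr1") {
  if (abs(rho) > 1) stop("|rho| must be at most 1")
  v <- trace$value
  n <- length(v)
  z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(0, n)
  with_preserved_seed(seed, {
    eps <- stats::rnorm(n)
    y <- rho * z + sqrt(1 - rho^2) * eps
    ab <- pmax(0, base + scale * y)
    expression_track(data.frame(chrom = chrom,
                                start = (0:(n - 1L)) * bin_bp,
                                end = (1:n) * bin_bp,
                                abundance = ab))
  })
}

#' Random contact set
#'
#' Uniformly sampled admissible contacts (`j >= i + 2`, deduplicated) on a
#' chain; handy for property checks and as a light-weight null.
#'
#' @param n_beads chain length.
#' @param n_contacts_target number of contacts to draw (without
#'   replacement from all admissible pairs).
#' @param seed RNG seed.
#' @return a [ct_contacts].
#' @export
random_contacts <- function(n_beads, n_contacts_target, seed = NULL) {
  total <- (n_beads - 2L) * (n_beads - 1L) / 2L  # pairs with j >= i + 2
  if (n_contacts_target > total)
    stop("requested more contacts than admissible pairs")
  with_preserved_seed(seed, {
    # enumerate admissible pairs lazily via index arithmetic on a sample
    i <- rep.int(0:(n_beads - 3L), times = (n_beads - 2L):1L)
    j <- unlist(lapply(0:(n_beads - 3L), function(a) (a + 2L):(n_beads - 1L)))
    pick <- sample.int(length(i), n_contacts_target)
    ct_contacts(i[pick], j[pick], n_beads = n_beads, source = "synthetic")
  })
}
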