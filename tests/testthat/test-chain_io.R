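test_that("read_chain parses plain and labeled tables and rejects bad rows", {
  f <- withr_local_file <- tempfile(fileext = ".tsv")
  writeLines(c("0 0 0", "1 0 0", "2 0 0", "3 0 0"), f)
  ch <- read_chain(f)
  expect_s3_class(ch, "bead_chain")
  expect_equal(n_beads(ch), 4L)
  expect_equal(ch$coords[, 1], 0:3)

  writeLines(c("x y z", "chr1\t0\t0\t0", "chr1\t1\t2\t3"), f)
  ch2 <- read_chain(f)
  expect_equal(ch2$label, "chr1")
  expect_equal(unname(ch2$coords[2, ]), c(1, 2, 3))

  writeLines(c("0 0 0", "1 oops 0", "2 0 0"), f)
  expect_error(read_chain(f), "line 2")

  writeLines("0 0 0", f)
  expect_error(read_chain(f), "at least 2 beads")
  unlink(f)
})

test_that("write_chain/read_chain round-trips coordinates bit-exactly", {
  set.seed(7)
  ch <- bead_chain(matrix(rnorm(30), 10, 3), label = "rt")
  f <- tempfile()
  write_chain(ch, f)
  back <- read_chain(f)
  expect_identical(back$coords, ch$coords)
  expect_identical(back$label, "rt")
  unlink(f)
})

test_that("extract_contacts applies the cutoff and first-neighbor exclusion", {
  rod <- bead_chain(cbind(0:3, 0, 0))
  expect_equal(n_contacts(extract_contacts(rod, 1.0)), 0L)

  hairpin <- bead_chain(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0.8, 0), c(0, 0.8, 0)))
  cs <- extract_contacts(hairpin, 1.0)
  expect_equal(cbind(cs$i, cs$j), cbind(0L, 3L))

  # beads 0 and 1 close in space: still excluded as first neighbors
  pair <- bead_chain(rbind(c(0, 0, 0), c(0.5, 0, 0), c(10, 0, 0)))
  expect_equal(n_contacts(extract_contacts(pair, 1.0)), 0L)

  expect_error(extract_contacts(rod, 0), "positive")
})

test_that("extract_contacts is rigid-motion invariant and monotone in r_c", {
  set.seed(42)
  ch <- random_chain(60, box = c(5, 5, 5), seed = 11)
  # cutoff strictly between the lattice distances 1 and sqrt(2), so the
  # comparison is boundary-safe under floating-point rotation
  cs1 <- extract_contacts(ch, 1.2)
  # random rotation (QR of a random matrix) + translation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_); if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- bead_chain(ch$coords %*% R + matrix(c(3, -2, 7), n_beads(ch), 3,
                                               byrow = TRUE))
  cs2 <- extract_contacts(moved, 1.2)
  expect_equal(cs1$i, cs2$i)
  expect_equal(cs1$j, cs2$j)

  for (rc in c(0.5, 1.0, 1.5)) {
    a <- extract_contacts(ch, rc); b <- extract_contacts(ch, rc + 0.5)
    expect_true(all(paste(a$i, a$j) %in% paste(b$i, b$j)))
  }
})

test_that("contacts_from_hic thresholds counts and excludes adjacent bins", {
  m <- matrix(0, 5, 5)
  m[1, 4] <- m[4, 1] <- 300
  cs <- contacts_from_hic(m, threshold = 250)
  expect_equal(cbind(cs$i, cs$j), cbind(0L, 3L))
  expect_equal(n_contacts(contacts_from_hic(m, threshold = 301)), 0L)

  m2 <- matrix(0, 5, 5); m2[1, 2] <- m2[2, 1] <- 999
  expect_equal(n_contacts(contacts_from_hic(m2, threshold = 250)), 0L)

  expect_error(contacts_from_hic(matrix(0, 3, 4)), "square")

  # upper-triangle-only storage is mirrored, not rejected
  m3 <- matrix(0, 5, 5); m3[1, 4] <- 500
  expect_equal(n_contacts(contacts_from_hic(m3, threshold = 250)), 1L)

  # COO input, 1-based bins
  coo <- data.frame(bin_i = c(1, 2), bin_j = c(4, 5), count = c(260, 100))
  cs3 <- contacts_from_hic(coo, threshold = 250, n_bins = 5)
  expect_equal(cbind(cs3$i, cs3$j), cbind(0L, 3L))
})

test_that("contacts_from_hic is monotone non-increasing in threshold", {
  set.seed(3)
  m <- matrix(rpois(400, 150), 20, 20)
  m <- pmax(m, t(m))
  prev <- NULL
  for (thr in c(100, 200, 300)) {
    cs <- contacts_from_hic(m, threshold = thr)
    if (!is.null(prev))
      expect_true(all(paste(cs$i, cs$j) %in% prev))
    prev <- paste(cs$i, cs$j)
  }
})

test_that("contact_midpoints uses bin midpoints", {
  cs <- ct_contacts(0L, 3L, n_beads = 5L)
  mp <- contact_midpoints(cs, bin_bp = 1e5)
  expect_equal(unname(mp[1, ]), c(0.5e5, 3.5e5))
})

test_that("expression tracks are sorted, validated, and reject overlaps", {
  f <- tempfile()
  writeLines(c("chr1\t1000000\t2000000\t20", "chr1\t0\t1000000\t10"), f)
  tr <- read_expression(f)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$start, c(0, 1e6))  # sorted on read

  writeLines(c("chr1\t0\t1000000\t10", "chr1\t500000\t1500000\t5"), f)
  expect_error(read_expression(f), "overlapping")
  unlink(f)
})

test_that("contact set constructor sorts, dedupes and validates", {
  cs <- ct_contacts(c(5L, 0L, 0L), c(9L, 3L, 3L), n_beads = 10L)
  expect_equal(cs$i, c(0L, 5L))
  expect_equal(cs$j, c(3L, 9L))
  expect_error(ct_contacts(0L, 1L, n_beads = 5L), "first-neighbor")
  expect_error(ct_contacts(0L, 9L, n_beads = 5L), "beyond chain")
})
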