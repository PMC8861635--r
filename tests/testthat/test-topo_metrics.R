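fixture_matrix <- function() build_topology_matrix(lloop_fixture())

test_that("entangled_fraction spans pure series to fully entangled", {
  series <- build_topology_matrix(ct_contacts(c(0L, 4L), c(3L, 7L), 10L))
  expect_equal(entangled_fraction(series), 0)
  crossing <- build_topology_matrix(ct_contacts(c(0L, 2L), c(4L, 6L), 10L))
  expect_equal(entangled_fraction(crossing), 1)
  expect_equal(entangled_fraction(fixture_matrix()), 27 / 36)
  single <- build_topology_matrix(ct_contacts(0L, 3L, 10L))
  expect_error(entangled_fraction(single), "undefined")
})

test_that("contact_entanglement counts full-row entangled partners", {
  series <- build_topology_matrix(ct_contacts(c(0L, 4L), c(3L, 7L), 10L))
  expect_equal(contact_entanglement(series), c(0, 0))
  crossing <- build_topology_matrix(ct_contacts(c(0L, 2L), c(4L, 6L), 10L))
  expect_equal(contact_entanglement(crossing), c(1, 1))
  # oracle-enumerated row counts for the nine-contact fixture
  expect_equal(contact_entanglement(fixture_matrix()),
               c(8, 8, 2, 7, 7, 4, 6, 6, 6))
})

test_that("entanglement identities hold on random contact sets", {
  for (rep in 1:10) {
    cs <- random_contacts(100, 40, seed = 100 + rep)
    m <- build_topology_matrix(cs)
    rows <- contact_entanglement(m)
    n <- nrow(m)
    expect_equal(entangled_fraction(m), sum(rows) / (n * (n - 1)))
    tr <- site_entanglement_trace(cs, rows)
    expect_equal(sum(tr$value), 2 * sum(rows))
    expect_true(entangled_fraction(m) >= 0 && entangled_fraction(m) <= 1)
  }
})

test_that("adding an all-series contact strictly decreases the entangled fraction", {
  cs <- random_contacts(50, 15, seed = 77)
  m <- build_topology_matrix(cs)
  f0 <- entangled_fraction(m)
  expect_true(f0 > 0)
  # append a contact beyond the existing chain span: series with everything
  cs2 <- ct_contacts(c(cs$i, 52L), c(cs$j, 55L), n_beads = 60L)
  f1 <- entangled_fraction(build_topology_matrix(cs2))
  expect_lt(f1, f0)
})

test_that("site trace credits both endpoints and leaves bare beads at zero", {
  cs <- ct_contacts(c(0L, 2L), c(4L, 6L), 10L)
  m <- build_topology_matrix(cs)
  tr <- site_entanglement_trace(cs, contact_entanglement(m))
  expect_equal(tr$value[c(1, 3, 5, 7)], c(1, 1, 1, 1))  # beads 0,2,4,6
  expect_equal(tr$value[c(2, 4, 6, 8, 9, 10)], rep(0, 6))

  fix <- lloop_fixture()
  trf <- site_entanglement_trace(fix, contact_entanglement(fixture_matrix()))
  expect_equal(trf$value[1], 8)  # bead 0: endpoint of contact 1 only
})

test_that("bin_trace sums beads into genomic bins and validates sizes", {
  tr <- ct_trace(0:19, rep(1, 20))
  b <- bin_trace(tr, 1e6)
  expect_equal(b$value, c(10, 10))
  expect_equal(b$position, c(0, 1e6))
  expect_error(bin_trace(tr, 5e4), "smaller than")
  empty <- ct_trace(0:19, rep(0, 20))
  expect_equal(bin_trace(empty, 1e6)$value, c(0, 0))
})

test_that("contact-level binning credits the first site's bin", {
  cs <- ct_contacts(5L, 95L, n_beads = 100L)
  binned <- entanglement_by_bin(cs, 3, bin_bp = 1e6)
  expect_equal(binned$value[1], 3)
  expect_equal(sum(binned$value[-1]), 0)
  expect_equal(nrow(binned), 10L)
})

test_that("expression correlation recovers exact and planted correlations", {
  tr <- ct_trace((0:199) * 10, sin(1:200) + 2)  # 200 1 Mb bins as beads*10
  binned <- bin_trace(tr, 1e6)
  # exact linear transform -> r = 1 (floor disabled to keep it exact)
  track <- expression_track(data.frame(chrom = "chr1",
                                       start = (0:199) * 1e6,
                                       end = (1:200) * 1e6,
                                       abundance = 100 + 50 * binned$value))
  res <- correlate_with_expression(binned, track, abundance_floor = 0)
  expect_equal(res$r, 1)

  # planted rho = 0.6 at n = 200 bins recovered within sampling error
  res2 <- correlate_with_expression(
    binned, synthetic_expression(binned, rho = 0.6, seed = 31))
  expect_lt(abs(res2$r - 0.6), 0.15)

  const <- expression_track(data.frame(chrom = "chr1", start = (0:199) * 1e6,
                                       end = (1:200) * 1e6, abundance = 100))
  expect_error(correlate_with_expression(binned, const), "constant")
})

test_that("radius of gyration matches closed forms", {
  same <- bead_chain(matrix(1, 4, 3))
  expect_equal(radius_of_gyration(same), 0)
  two <- bead_chain(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two), 1)
  rod <- bead_chain(cbind(0:3, 0, 0))
  expect_equal(radius_of_gyration(rod), sqrt(5) / 2)
})

test_that("entanglement contact map mirrors row counts symmetrically", {
  cs <- lloop_fixture()
  rows <- contact_entanglement(fixture_matrix())
  hm <- entanglement_contact_map(cs, rows)
  expect_equal(hm[1, 121], 8)  # contact 1 at (0, 120), 1-based cells
  expect_equal(hm, t(hm))
  expect_equal(sum(hm > 0), 18)
})
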