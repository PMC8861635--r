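test_that("cumulative scans saturate once all contacts are inside the window", {
  # all contacts within beads 0..20 of a 60-bead chain
  cs <- ct_contacts(c(0L, 2L, 5L), c(10L, 8L, 20L), 60L)
  ws <- cumulative_scan(cs, metric = "entangled_fraction")
  expect_equal(ws$window, seq(5, 60, 5))
  vals <- ws$value[ws$window >= 25]
  expect_true(all(vals == vals[1]))
  # last window equals the whole-chain metric exactly
  expect_equal(ws$value[nrow(ws)],
               entangled_fraction(build_topology_matrix(cs)))
})

test_that("windows with fewer than two contacts yield NA", {
  cs <- ct_contacts(c(0L, 30L), c(2L, 35L), 60L)
  ws <- cumulative_scan(cs)
  expect_true(all(is.na(ws$value[ws$window < 36])))
  expect_equal(ws$value[ws$window >= 40], rep(0, 5))
  expect_error(cumulative_scan(cs, metric = "typo"), "arg")
})

test_that("direction reversal mirrors the series for a mirror-symmetric set", {
  nb <- 60L
  i <- c(2L, 6L, 10L); j <- c(12L, 20L, 30L)
  sym <- ct_contacts(c(i, nb - 1L - j), c(j, nb - 1L - i), n_beads = nb)
  lr <- cumulative_scan(sym, direction = "left_to_right")
  rl <- cumulative_scan(sym, direction = "right_to_left")
  expect_equal(lr$value, rl$value)
})

test_that("polynomial smoothing passes constants and quadratics exactly", {
  const <- rep(0.4, 40)
  expect_equal(smooth_series(const), const)
  t <- 1:40
  quad <- 0.01 * t^2 - 0.3 * t + 2
  expect_equal(smooth_series(quad), quad, tolerance = 1e-10)
  expect_warning(short <- smooth_series(1:5), "shorter")
  expect_equal(short, 1:5)
  # step response overshoot is bounded by the step amplitude
  step <- c(rep(0, 30), rep(1, 30))
  sm <- smooth_series(step)
  expect_true(all(sm > -1 & sm < 2))
})

test_that("find_peaks honors topographic prominence", {
  expect_length(find_peaks(seq(0, 1, length.out = 50)), 0)  # monotone

  t <- 0:399
  sine <- 0.5 + 0.5 * sin(2 * pi * t / 100)
  pk <- find_peaks(sine, prominence = 0.2)
  expect_true(all(abs(diff(pk)) >= 95 & abs(diff(pk)) <= 105))

  weak <- 0.5 + 0.05 * sin(2 * pi * t / 100)
  expect_length(find_peaks(weak, prominence = 0.2), 0)
})

test_that("peak spacing reports consecutive gaps and their mode", {
  sp <- peak_spacing(c(100, 200, 300))
  expect_equal(sp$spacings_beads, c(100, 100))
  expect_equal(sp$modal_beads, 100)
  expect_equal(sp$modal_mb, 10)
  expect_error(peak_spacing(150), "insufficient")

  tr <- periodic_trace(110, 0.5, 0, n = 550, seed = 1)
  pk <- find_peaks(smooth_series(tr), prominence = 0.2)
  sp2 <- peak_spacing(pk)
  expect_true(sp2$modal_beads >= 100 && sp2$modal_beads <= 120)
})

test_that("planted periodicities are recovered within 10 beads in >= 90% of replicates", {
  hits <- 0L; total <- 0L
  for (period in c(80, 110, 140)) {
    for (rep in 1:50) {
      tr <- periodic_trace(period, amplitude = 0.3, noise_sd = 0.05,
                           n = 5 * period, seed = period * 1000 + rep)
      sm <- smooth_series(tr, window = 15, degree = 2)
      pk <- find_peaks(sm, prominence = 0.2)
      total <- total + 1L
      if (length(pk) >= 2L &&
          abs(peak_spacing(pk)$modal_beads - period) <= 10) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("peak positions are invariant to adding a constant", {
  tr <- periodic_trace(100, 0.4, 0.03, n = 400, seed = 5)
  sm <- smooth_series(tr)
  shifted <- sm; shifted$value <- shifted$value + 3
  expect_equal(as.numeric(find_peaks(sm)), as.numeric(find_peaks(shifted)))
})

test_that("convergence threshold finds the plateau start", {
  flat <- structure(data.frame(window = seq(5, 100, 5), value = 1.2),
                    class = c("window_series", "data.frame"))
  expect_equal(convergence_threshold(flat), 5)

  v <- c(seq(2, 1.3, length.out = 10), rep(1.25, 10))
  conv <- structure(data.frame(window = seq(5, 100, 5), value = v),
                    class = c("window_series", "data.frame"))
  # values within 5% of 1.25 only from the plateau onward
  expect_equal(convergence_threshold(conv),
               conv$window[min(which(abs(v - 1.25) / 1.25 <= 0.05))])

  osc <- structure(data.frame(window = seq(5, 100, 5),
                              value = rep(c(2, 1), 10)),
                   class = c("window_series", "data.frame"))
  res <- convergence_threshold(osc)
  expect_equal(as.numeric(res), 100)
  expect_true(isTRUE(attr(res, "no_plateau")))
})
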