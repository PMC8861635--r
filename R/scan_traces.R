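#' Cumulative-window scan of a circuit-topology metric
#'
#' Windows of increasing size (step 5 beads: 5, 10, ..., n) are grown from
#' one end of the chain; within each window the contacts having *both*
#' endpoints inside it are kept, the topology matrix is rebuilt, and the
#' requested metric is evaluated. Windows with fewer than two contacts yield
#' `NA`. The final window spans the whole chain, so the last value equals
#' the whole-chain metric exactly.
#'
#' @param contacts a [ct_contacts].
#' @param metric `"entangled_fraction"` or `"fractal_D"`.
#' @param direction `"left_to_right"` (grow from bead 0) or
#'   `"right_to_left"`.
#' @param step window increment in beads (default 5).
#' @param entangled entangled relation set used by both metrics.
#' @return a `window_series` data frame with columns `window` (beads) and
#'   `value`; metric and direction kept as attributes.
#' @export
cumulative_scan <- function(contacts,
                            metric = c("entangled_fraction", "fractal_D"),
                            direction = c("left_to_right", "right_to_left"),
                            step = 5L, entangled = entangled_set()) {
  metric <- match.arg(metric)
  direction <- match.arg(direction)
  n <- contacts$n_beads
  if (n < 10L) stop("chain too short for a cumulative scan (need >= 10 beads)")
  windows <- seq(step, n, by = step)
  if (windows[length(windows)] != n) windows <- c(windows, n)
  vals <- vapply(windows, function(w) {
    if (direction == "left_to_right") {
      keep <- contacts$j <= w - 1L
    } else {
      keep <- contacts$i >= n - w
    }
    if (sum(keep) < 2L) return(NA_real_)
    sub <- ct_contacts(contacts$i[keep], contacts$j[keep], n_beads = n,
                       source = contacts$source)
    m <- build_topology_matrix(sub)
    if (metric == "entangled_fraction") {
      entangled_fraction(m, entangled)
    } else {
      box_count_dimension(binarize_entangled(m, entangled))$D
    }
  }, numeric(1))
  structure(data.frame(window = windows, value = vals),
            class = c("window_series", "data.frame"),
            metric = metric, direction = direction, step = step)
}

#' Smooth a series with a local least-squares polynomial filter
#'
#' Degree-2 polynomial smoothing on a 15-bead window by default
#' (Savitzky-Golay-type filter). Near the edges the fit window shrinks
#' symmetrically, so the filter still passes polynomials of the given degree
#' exactly. `NA` values are left in place and excluded from neighboring
#' fits.
#'
#' @param series a `window_series`, [ct_trace], or numeric vector.
#' @param window odd window length in samples (default 15).
#' @param degree polynomial degree (default 2).
#' @return the input with its values replaced by smoothed values.
#' @export
smooth_series <- function(series, window = 15L, degree = 2L) {
  x <- series_values(series)
  n <- length(x)
  if (n < window) {
    warning("series shorter than the smoothing window: returned unsmoothed")
    return(series)
  }
  half <- (window - 1L) %/% 2L
  out <- x
  for (t in seq_len(n)) {
    if (is.na(x[t])) next
    h <- min(half, t - 1L, n - t)
    idx <- (t - h):(t + h)
    idx <- idx[!is.na(x[idx])]
    if (length(idx) < degree + 1L) next
    z <- idx - t
    X <- stats::poly(z, degree = min(degree, length(idx) - 1L), raw = TRUE)
    fit <- stats::lm.fit(cbind(1, X), x[idx])
    out[t] <- unname(fit$coefficients[1L])
  }
  series_replace_values(series, out)
}

# value accessors shared by window_series / ct_trace / numeric
series_values <- function(series) {
  if (is.numeric(series)) series else series$value
}
series_positions <- function(series) {
  if (is.numeric(series)) seq_along(series)
  else if (!is.null(series$window)) series$window
  else series$position
}
series_replace_values <- function(series, v) {
  if (is.numeric(series)) return(v)
  series$value <- v
  series
}

#' Find local maxima by topographic prominence
#'
#' A sample is a peak when it exceeds its neighbors (the first sample of a
#' plateau represents the plateau). Its prominence is its height minus the
#' higher of the two lowest points that must be crossed to reach higher
#' terrain (or the series border) on each side. Peaks with prominence below
#' the threshold are discarded.
#'
#' @param series a `window_series`, [ct_trace] or numeric vector (usually
#'   smoothed first).
#' @param prominence minimum topographic prominence (default 0.2, on the
#'   natural \[0, 1\] scale of the entangled fraction).
#' @return positions of the retained peaks (window sizes / trace positions
#'   for series input, indices for numeric input), with the indices and
#'   prominences as attributes.
#' @export
find_peaks <- function(series, prominence = 0.2) {
  x <- series_values(series)
  pos <- series_positions(series)
  n <- length(x)
  cand <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (!is.na(x[i]) && !is.na(x[i - 1L]) && x[i] > x[i - 1L]) {
      # walk over a possible plateau
      k <- i
      while (k < n && !is.na(x[k + 1L]) && x[k + 1L] == x[i]) k <- k + 1L
      if (k < n && !is.na(x[k + 1L]) && x[k + 1L] < x[i]) cand <- c(cand, i)
      i <- k + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) {
    out <- pos[integer()]
    attr(out, "indices") <- integer(); attr(out, "prominences") <- numeric()
    return(out)
  }
  prom <- vapply(cand, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    hi <- which(left > h)
    lmin <- min(left[seq.int(if (length(hi)) max(hi) + 1L else 1L, p - 1L)],
                na.rm = TRUE)
    right <- x[seq.int(p + 1L, n)]
    hi <- which(right > h)
    rmin <- min(right[seq_len(if (length(hi)) min(hi) - 1L else length(right))],
                na.rm = TRUE)
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= prominence
  out <- pos[cand[keep]]
  attr(out, "indices") <- cand[keep]
  attr(out, "prominences") <- prom[keep]
  out
}

#' Spacing statistics of detected peaks
#'
#' Consecutive peak-to-peak distances and their modal value. The mode is
#' taken over spacings rounded to the nearest `bin_beads` (a histogram of
#' 10-bead bins by default); ties resolve to the smaller spacing.
#'
#' @param positions peak positions in beads, from [find_peaks()].
#' @param bin_beads histogram bin width in beads.
#' @param bead_bp bead size in bp, for the Mb conversion.
#' @return list with `spacings_beads`, `spacings_mb`, `modal_beads`,
#'   `modal_mb`.
#' @export
peak_spacing <- function(positions, bin_beads = 10, bead_bp = 1e5) {
  positions <- as.numeric(positions)
  if (length(positions) < 2L) stop("insufficient peaks (need at least 2)")
  sp <- diff(positions)
  rounded <- round(sp / bin_beads) * bin_beads
  tab <- table(rounded)
  best <- max(tab)
  modal <- min(as.numeric(names(tab)[tab == best]))
  list(spacings_beads = sp,
       spacings_mb = sp * bead_bp / 1e6,
       modal_beads = modal,
       modal_mb = modal * bead_bp / 1e6)
}

#' Convergence threshold of a fractal-dimension trace
#'
#' Smallest window size `W` such that every window `w >= W` has its value
#' within a relative tolerance of the full-chain value. If no window
#' satisfies this (other than the last), the full chain length is returned
#' with attribute `no_plateau = TRUE`.
#'
#' @param series a `window_series` (typically `metric = "fractal_D"`).
#' @param tol relative tolerance (default 0.05).
#' @return the window size `W` in beads.
#' @export
convergence_threshold <- function(series, tol = 0.05) {
  v <- series$value
  w <- series$window
  ref <- v[length(v)]
  if (is.na(ref) || ref == 0) stop("full-chain value undefined or zero")
  ok <- !is.na(v) & abs(v - ref) / abs(ref) <= tol
  bad <- which(!ok)
  if (!length(bad)) return(w[1L])
  last_bad <- max(bad)
  if (last_bad == length(v)) {  # cannot happen (ref == itself) but guard
    out <- w[length(w)]; attr(out, "no_plateau") <- TRUE; return(out)
  }
  out <- w[last_bad + 1L]
  if (last_bad + 1L == length(v)) attr(out, "no_plateau") <- TRUE
  out
}

#' Write a window scan (optionally with smoothed values) as TSV
#' @param series a `window_series`.
#' @param path output file.
#' @param smoothed optional smoothed companion series.
#' @param bead_bp bead size in bp.
#' @export
write_scan_tsv <- function(series, path, smoothed = NULL, bead_bp = 1e5) {
  df <- data.frame(window_beads = series$window,
                   window_mb = series$window * bead_bp / 1e6,
                   value = series$value)
  if (!is.null(smoothed)) df$smoothed_value <- smoothed$value
  write_tsv_plain(df, path)
}
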