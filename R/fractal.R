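#' Binarize a topology matrix into its entangled set
#'
#' Each matrix element is reassigned 1 or 0 according to whether it holds an
#' entangled or unentangled relation. The resulting binary matrix is the
#' fractal set over which the box-counting dimension is computed.
#'
#' @param m a `topology_matrix`.
#' @param entangled relation names mapped to 1 (default [entangled_set()]).
#' @return square 0/1 integer matrix with zero diagonal; the code set used
#'   is recorded in `attr(, "entangled")`.
#' @export
binarize_entangled <- function(m, entangled = entangled_set()) {
  stopifnot(inherits(m, "topology_matrix"))
  b <- matrix(as.integer(m %in% codes_of(entangled)), nrow(m))
  attr(b, "entangled") <- entangled
  b
}

#' Box-counting (Minkowski-Bouligand) fractal dimension of a binary matrix
#'
#' The matrix is zero-padded to the next power of two; for box sizes
#' `l = 1, 2, 4, ..., n_pad/2` the number `N(l)` of boxes containing at
#' least one set cell is counted, and `D` is the least-squares slope of
#' `log N(l)` versus `log(1/l)`. Saturated scales (`N(l) = 1` or
#' `N(l) =` total set cells) are dropped from the fit to avoid plateau bias.
#' The raw slope is clamped to \[0, 2\] with a diagnostic note if it falls
#' outside.
#'
#' @param b 0/1 matrix (e.g. from [binarize_entangled()]); any nonzero cell
#'   counts as set.
#' @return object of class `fractal_result`: list with `D`, `box_sizes`,
#'   `counts`, `slope_raw`, `intercept`, `r_squared`, `n_set`, `note`.
#' @export
box_count_dimension <- function(b) {
  b <- unclass(b) != 0
  n_set <- sum(b)
  note <- character()
  if (n_set == 0L) {
    warning("all-zero matrix: dimension defined as 0")
    return(structure(list(D = 0, box_sizes = integer(), counts = integer(),
                          slope_raw = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n_set = 0L,
                          note = "empty set"),
                     class = "fractal_result"))
  }
  n <- max(dim(b))
  n_pad <- 2^ceiling(log2(max(2L, n)))
  m <- matrix(FALSE, n_pad, n_pad)
  m[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  sizes <- integer(); counts <- integer()
  l <- 1L
  while (l <= n_pad / 2L) {
    sizes <- c(sizes, l); counts <- c(counts, sum(m))
    # merge 2x2 blocks: any set cell marks the parent box
    nr <- nrow(m)
    m <- m[seq(1L, nr, 2L), , drop = FALSE] | m[seq(2L, nr, 2L), , drop = FALSE]
    nc <- ncol(m)
    m <- m[, seq(1L, nc, 2L), drop = FALSE] | m[, seq(2L, nc, 2L), drop = FALSE]
    l <- l * 2L
  }
  valid <- counts > 1L & counts < n_set
  if (sum(valid) < 2L) {
    # degenerate geometry (single cell, or too small to scale): fall back to
    # all informative scales; a pure point still yields slope 0
    valid <- counts >= 1L
    if (length(unique(counts[valid])) < 2L) {
      return(structure(list(D = 0, box_sizes = sizes, counts = counts,
                            slope_raw = 0, intercept = log(n_set),
                            r_squared = NA_real_, n_set = n_set,
                            note = "degenerate set: no scaling range"),
                       class = "fractal_result"))
    }
  }
  x <- -log(sizes[valid]); y <- log(counts[valid])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  r2 <- if (length(y) > 2L) {
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  } else NA_real_
  D <- min(max(slope, 0), 2)
  if (slope < -1e-8 || slope > 2 + 1e-8) {
    note <- sprintf("raw slope %.3f outside [0, 2]; clamped", slope)
    warning(note)
  }
  structure(list(D = D, box_sizes = sizes, counts = counts,
                 slope_raw = slope, intercept = unname(fit$coefficients[1L]),
                 r_squared = r2, n_set = n_set,
                 note = if (length(note)) note else ""),
            class = "fractal_result")
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf("<fractal_result> D = %.4f over %d set cells (R^2 = %s)\n",
              x$D, x$n_set,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Contact-count-normalized fractal dimension
#'
#' The raw dimension correlates with the number of contacts; dividing by N
#' makes chromosomes of different contact counts comparable.
#'
#' @param f a `fractal_result` (or a bare dimension value).
#' @param n_contacts number of contacts N (>= 1).
#' @export
normalized_dimension <- function(f, n_contacts) {
  if (n_contacts < 1L) stop("n_contacts must be at least 1")
  D <- if (inherits(f, "fractal_result")) f$D else f
  D / n_contacts
}

#' Export a fractal result as JSON
#' @param f a `fractal_result`.
#' @param path output file.
#' @export
write_fractal_json <- function(f, path) {
  jsonlite::write_json(unclass(f), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
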