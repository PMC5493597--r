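# Frequencies (cycles per physical unit) along one FFT axis, in the
# unshifted DFT ordering: 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1,
# all divided by n * pixel_size. The single conversion from index units to
# physical units happens here.
fft_frequencies <- function(n, pixel_size) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * pixel_size)
}

#' Construct a radial spatial-frequency grid
#'
#' Log-spaced bins spanning the fundamental frequency of the image (one
#' cycle per largest extent) up to the Nyquist frequency `1/(2 px)`, in
#' cycles per micrometre. Bin centres are geometric midpoints of the
#' edges. The log spacing matches the log-frequency abscissa on which
#' results are plotted and compared.
#'
#' @param shape Image shape `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param n_bins Number of radial bins (>= 8).
#' @return An object of class `radial_grid` with `frequencies` (bin
#'   centres, strictly increasing, cycles/um) and `bin_edges`
#'   (length `n_bins + 1`).
#' @examples
#' g <- native_radial_grid(c(128, 128), pixel_size_um = 2, n_bins = 60)
#' range(g$bin_edges)   # 1/256 ... 0.25 cycles/um
#' @export
native_radial_grid <- function(shape, pixel_size_um, n_bins = 60) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 8L) stop("`n_bins` must be >= 8")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  f_min <- 1 / (max(shape) * pixel_size_um)
  f_max <- 1 / (2 * pixel_size_um)
  radial_grid_from_range(f_min, f_max, n_bins)
}

radial_grid_from_range <- function(f_min, f_max, n_bins) {
  if (!(f_min > 0) || !(f_max > f_min))
    stop("invalid frequency range [", f_min, ", ", f_max, "]")
  edges <- exp(seq(log(f_min), log(f_max), length.out = n_bins + 1))
  structure(list(frequencies = sqrt(edges[-1] * edges[-(n_bins + 1)]),
                 bin_edges = edges),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  n <- length(x$frequencies)
  cat(sprintf(
    "<radial_grid> %d log-spaced bins, %.4g - %.4g cycles/um (%.4g - %.4g um)\n",
    n, x$bin_edges[1], x$bin_edges[n + 1],
    1 / x$bin_edges[n + 1], 1 / x$bin_edges[1]))
  invisible(x)
}

same_grid <- function(g1, g2) {
  length(g1$frequencies) == length(g2$frequencies) &&
    isTRUE(all.equal(g1$bin_edges, g2$bin_edges, tolerance = 1e-12))
}

# Map every 2D DFT cell of a given image shape to its radial bin.
# Returns integer vector over the flattened matrix: bin index in
# 1..n_bins, or 0 for excluded cells (DC, and radii outside the edges —
# notably the grid corners beyond Nyquist). Cached per (shape, px, grid).
.radial_cache <- new.env(parent = emptyenv())

radial_bin_map <- function(shape, pixel_size_um, grid) {
  key <- paste(shape[1], shape[2], pixel_size_um,
               length(grid$frequencies),
               format(grid$bin_edges[1], digits = 17),
               format(grid$bin_edges[length(grid$bin_edges)], digits = 17),
               sep = "|")
  bm <- .radial_cache[[key]]
  if (!is.null(bm)) return(bm)
  fr <- fft_frequencies(shape[1], pixel_size_um)
  fc <- fft_frequencies(shape[2], pixel_size_um)
  r <- sqrt(outer(fr^2, fc^2, "+"))
  edges <- grid$bin_edges
  # tolerate rounding at the boundary edges
  eps <- 1e-9 * edges[length(edges)]
  rv <- as.vector(r)
  bin <- findInterval(rv, edges, rightmost.closed = TRUE)
  bin[bin == 0L & rv > 0 & rv >= edges[1] - eps] <- 1L
  bin[rv <= 0] <- 0L
  bin[bin > length(grid$frequencies)] <- 0L
  bin[rv > edges[length(edges)] + eps] <- 0L
  counts <- tabulate(bin[bin > 0L], nbins = length(grid$frequencies))
  bm <- list(bin = bin, counts = counts)
  .radial_cache[[key]] <- bm
  bm
}

#' Number of 2D Fourier cells pooled into each radial bin
#'
#' Useful for identifying sparse bins (at low radial frequency a log bin
#' may contain no or very few 2D frequencies) when selecting which bins to
#' trust for distributional statements.
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param grid A [native_radial_grid].
#' @return Integer vector, one count per bin.
#' @export
radial_bin_counts <- function(shape, pixel_size_um, grid) {
  radial_bin_map(shape, pixel_size_um, grid)$counts
}

radial_function <- function(grid, values, mask = !is.finite(values)) {
  structure(list(grid = grid, values = values, mask = mask),
            class = "radial_function")
}

#' Circularly average a 2D frequency-domain field
#'
#' Averages the field over all orientations: each radial bin receives the
#' unweighted mean of the field at every 2D frequency whose radius
#' `sqrt(fx^2 + fy^2)` falls inside the bin. The DC cell is always
#' excluded, as are corner frequencies beyond the Nyquist radius. Bins
#' containing no 2D frequency are masked.
#'
#' @param field Real matrix on the native (unshifted) 2D DFT grid of an
#'   image, e.g. one 2D log-spectrum or atanh-coherence map.
#' @param grid A [native_radial_grid] for the same shape and pixel size.
#' @param pixel_size_um Pixel size of the image the field came from.
#' @return An object of class `radial_function` with `grid`, `values`
#'   (NA where masked) and logical `mask`.
#' @export
circular_average <- function(field, grid, pixel_size_um) {
  stopifnot(is.matrix(field), inherits(grid, "radial_grid"))
  bm <- radial_bin_map(dim(field), pixel_size_um, grid)
  vals <- radial_means(as.vector(field), bm, length(grid$frequencies))
  radial_function(grid, vals, mask = bm$counts == 0L)
}

# workhorse shared with the jackknife loops: mean of x per radial bin
radial_means <- function(x, bm, n_bins) {
  keep <- bm$bin > 0L
  sums <- rowsum(x[keep], bm$bin[keep])
  out <- rep(NA_real_, n_bins)
  ids <- as.integer(rownames(sums))
  out[ids] <- sums[, 1] / bm$counts[ids]
  out
}

#' Interpolate radial functions onto a shared frequency grid
#'
#' Functions estimated on different native grids (images of different
#' sizes have different fundamental frequencies) are brought onto one
#' common grid by linear interpolation in log-frequency. The shared grid
#' spans only the intersection of the unmasked frequency ranges; nothing
#' is ever extrapolated — out-of-range bins are masked.
#'
#' @param fns List of `radial_function` objects.
#' @param n_bins Number of bins of the shared grid; defaults to the
#'   largest input grid size.
#' @return List with `grid` (the shared [radial_grid]) and `values`
#'   (matrix, one row per input function; NA where masked).
#' @export
interpolate_to_common <- function(fns, n_bins = NULL) {
  stopifnot(length(fns) >= 1)
  grids <- lapply(fns, `[[`, "grid")
  if (all(vapply(grids[-1], same_grid, logical(1), g2 = grids[[1]]))) {
    vals <- do.call(rbind, lapply(fns, function(f)
      ifelse(f$mask, NA_real_, f$values)))
    return(list(grid = grids[[1]], values = vals))
  }
  lo <- max(vapply(grids, function(g) g$bin_edges[1], numeric(1)))
  hi <- min(vapply(grids, function(g)
    g$bin_edges[length(g$bin_edges)], numeric(1)))
  if (!(hi > lo))
    stop("radial grids have no overlapping frequency range")
  if (is.null(n_bins))
    n_bins <- max(vapply(grids, function(g) length(g$frequencies), integer(1)))
  shared <- radial_grid_from_range(lo, hi, n_bins)
  vals <- do.call(rbind, lapply(fns, function(f) {
    ok <- !f$mask & is.finite(f$values)
    if (sum(ok) < 2) return(rep(NA_real_, n_bins))
    stats::approx(x = log(f$grid$frequencies[ok]), y = f$values[ok],
                  xout = log(shared$frequencies), method = "linear",
                  rule = 1)$y
  }))
  list(grid = shared, values = vals)
}

#' Length scale corresponding to a spatial frequency
#'
#' The characteristic separation probed at frequency `f` is the period
#' `1/f`: power at 0.025 cycles/um means structures repeating every 40 um.
#'
#' @param frequency Positive spatial frequency (cycles/um); vectorized.
#' @return Length scale(s) in micrometres.
#' @export
length_scale_of <- function(frequency) {
  if (!is.numeric(frequency) || any(!is.finite(frequency)) ||
      any(frequency <= 0))
    stop("`frequency` must be positive and finite")
  1 / frequency
}
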