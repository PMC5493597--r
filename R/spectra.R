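# floor added inside the log so exactly-zero power bins stay finite;
# smallest normalized double, affects no bin with any signal
.log_floor <- 2.225074e-308
# coherence magnitude cap: atanh(1) diverges for self-coherent channels
.coh_cap <- 1 - 1e-6

#' Tapered 2D Fourier coefficients of a condition dataset
#'
#' For every image pair: subtract each channel's mean, multiply by each of
#' the M Slepian tapers, and apply the (unnormalized forward) 2D discrete
#' Fourier transform. The N x M tapered coefficient grids per channel are
#' the elementary spectral estimates everything downstream is built from;
#' with N images and M tapers the analysis carries NM degrees of freedom.
#' The DC cell is meaningless after mean subtraction and is excluded from
#' all downstream curves.
#'
#' @param dataset A [condition_dataset].
#' @param config An [analysis_config]; supplies the taper bandwidth and M.
#' @return An object of class `tapered_coefficients`: for each flat
#'   estimate index `u = (i-1)M + m` holds complex matrices `a` and `b`;
#'   plus `image_index`, `taper_index`, `shapes`, `pixel_size_um`, `N`,
#'   `M`, `NM`.
#' @export
tapered_coefficients <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "condition_dataset"),
            inherits(config, "analysis_config"))
  N <- dataset$n_images
  M <- config$n_tapers
  px <- dataset$pairs[[1]]$a$pixel_size_um
  estimates <- vector("list", N * M)
  image_index <- integer(N * M)
  taper_index <- integer(N * M)
  shapes <- vector("list", N)
  for (i in seq_len(N)) {
    pr <- dataset$pairs[[i]]
    d <- dim(pr$a$intensities)
    shapes[[i]] <- d
    ts <- get_taper_set(d[1], d[2], config$bandwidth_product, M)
    xa <- pr$a$intensities - mean(pr$a$intensities)
    xb <- pr$b$intensities - mean(pr$b$intensities)
    for (m in seq_len(M)) {
      u <- (i - 1L) * M + m
      w <- ts$tapers[[m]]
      estimates[[u]] <- list(a = stats::fft(xa * w), b = stats::fft(xb * w))
      image_index[u] <- i
      taper_index[u] <- m
    }
  }
  structure(list(estimates = estimates, image_index = image_index,
                 taper_index = taper_index, shapes = shapes,
                 pixel_size_um = px, N = N, M = M, NM = N * M),
            class = "tapered_coefficients")
}

#' @export
print.tapered_coefficients <- function(x, ...) {
  cat(sprintf("<tapered_coefficients> N = %d images x M = %d tapers = %d estimates\n",
              x$N, x$M, x$NM))
  invisible(x)
}

#' Per-estimate 2D log-spectra
#'
#' `log(|J|^2 + eps)` (natural log) for each of the NM tapered coefficient
#' grids of one channel — the "sets" of log-spectra that are later
#' circularly averaged and jackknifed. The tiny floor `eps` (smallest
#' normalized double) only matters for bins with exactly zero power.
#'
#' @param tc A [tapered_coefficients] object.
#' @param channel `"a"` or `"b"`.
#' @return List of NM real matrices.
#' @export
log_spectrum_2d <- function(tc, channel = c("a", "b")) {
  stopifnot(inherits(tc, "tapered_coefficients"))
  channel <- match.arg(channel)
  lapply(tc$estimates, function(e) log(Mod(e[[channel]])^2 + .log_floor))
}

# raw cross/auto products for one estimate
estimate_products <- function(e) {
  list(ab = e$a * Conj(e$b), aa = Mod(e$a)^2, bb = Mod(e$b)^2)
}

#' Pooled atanh-coherence across (image, taper) estimates
#'
#' The magnitude coherence at each 2D frequency is
#' `C(k) = |sum J_a J_b*| / sqrt(sum |J_a|^2 * sum |J_b|^2)`, pooled over
#' all retained (image, taper) estimates, followed by the
#' variance-stabilizing atanh transform (capped just below 1, since a
#' self-coherent bin would diverge). Pooling is essential: from a single
#' tapered estimate the normalized cross-spectrum is identically 1, so
#' coherence only becomes informative across the NM estimate set.
#' `leave_out` recomputes the pooled map with one estimate deleted — the
#' delete-one building block of the jackknife.
#'
#' All images must share one pixel grid; for mixed-size datasets the
#' pipeline pools per shape group and combines after circular averaging
#' (see [micasa_analyze]).
#'
#' @param tc A [tapered_coefficients] object (single image shape).
#' @param leave_out Optional flat estimate index in `1..NM` to delete.
#' @return Real matrix of atanh-coherence on the native 2D frequency grid.
#' @export
pooled_coherence <- function(tc, leave_out = NULL) {
  stopifnot(inherits(tc, "tapered_coefficients"))
  if (length(unique(vapply(tc$shapes, paste, character(1), collapse = "x"))) != 1L)
    stop("pooled_coherence requires a single image shape; ",
         "mixed-size datasets are pooled per shape group by micasa_analyze")
  keep <- seq_len(tc$NM)
  if (!is.null(leave_out)) {
    stopifnot(leave_out %in% keep)
    keep <- keep[-leave_out]
  }
  if (length(keep) < 2L)
    stop("coherence requires at least two (image, taper) estimates; ",
         "a single tapered estimate has coherence identically 1")
  d <- tc$shapes[[1]]
  Sab <- matrix(0 + 0i, d[1], d[2]); Saa <- matrix(0, d[1], d[2]); Sbb <- Saa
  for (u in keep) {
    p <- estimate_products(tc$estimates[[u]])
    Sab <- Sab + p$ab; Saa <- Saa + p$aa; Sbb <- Sbb + p$bb
  }
  coherence_map(Sab, Saa, Sbb)
}

coherence_map <- function(Sab, Saa, Sbb) {
  den <- sqrt(Saa * Sbb)
  C <- matrix(0, nrow(Sab), ncol(Sab))
  pos <- den > 0
  C[pos] <- Mod(Sab[pos]) / den[pos]
  atanh(pmin(C, .coh_cap))
}
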