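# EBImage wrappers: the region logic works on plain logical/numeric
# matrices; EBImage supplies thresholding, smoothing, distance transforms
# and connected-component labelling.
as_ebi <- function(m) EBImage::Image(m)

#' Whole-tissue mask from the two summed channels
#'
#' Otsu threshold of the normalized channel sum, with holes filled —
#' a simple foreground mask for whole-section images where tissue is
#' brighter than slide background.
#'
#' @param channel_a,channel_b [image_channel] objects of one pair.
#' @return Logical matrix, TRUE on tissue.
#' @export
tissue_mask <- function(channel_a, channel_b) {
  s <- channel_a$intensities + channel_b$intensities
  rng <- range(s)
  if (rng[2] <= rng[1]) return(matrix(FALSE, nrow(s), ncol(s)))
  s01 <- (s - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(as_ebi(s01))
  filled <- EBImage::fillHull(as_ebi(s01 > thr))
  matrix(as.logical(filled), nrow(s), ncol(s))
}

#' Segment the medulla from its marker channel
#'
#' Smooths the marker channel and thresholds it into a binary medulla
#' mask, then removes speckles below a minimum area. Otsu (default) and
#' quantile thresholds both operate on the normalized image, so the mask
#' is invariant to overall intensity rescaling. An all-background channel
#' yields an empty mask with a warning rather than an error.
#'
#' @param channel [image_channel] of the medullary marker (e.g. K14).
#' @param smoothing_um Gaussian smoothing sd in micrometres.
#' @param threshold_method `"otsu"` or `"quantile"`.
#' @param quantile For the quantile method, the probability cut.
#' @param min_area_um2 Connected components smaller than this are removed.
#' @return Logical matrix, TRUE on medulla.
#' @export
medulla_mask <- function(channel, smoothing_um = 20,
                         threshold_method = c("otsu", "quantile"),
                         quantile = 0.7, min_area_um2 = 400) {
  stopifnot(inherits(channel, "image_channel"))
  threshold_method <- match.arg(threshold_method)
  m <- channel$intensities
  px <- channel$pixel_size_um
  rng <- range(m)
  if (rng[2] <= rng[1]) {
    warning("channel has no contrast; returning an empty medulla mask")
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  m01 <- (m - rng[1]) / (rng[2] - rng[1])
  sm <- matrix(as.numeric(EBImage::gblur(as_ebi(m01),
                                         sigma = smoothing_um / px)),
               nrow(m), ncol(m))
  thr <- if (threshold_method == "otsu") {
    sm_rng <- range(sm)
    EBImage::otsu(as_ebi((sm - sm_rng[1]) /
                           max(sm_rng[2] - sm_rng[1], 1e-12))) *
      (sm_rng[2] - sm_rng[1]) + sm_rng[1]
  } else {
    stats::quantile(sm, probs = quantile, names = FALSE)
  }
  mask <- sm > thr
  # speck removal
  lab <- EBImage::bwlabel(as_ebi(mask))
  sizes <- tabulate(as.integer(lab))
  min_px <- max(1L, floor(min_area_um2 / px^2))
  keep <- which(sizes >= min_px)
  matrix(as.integer(lab) %in% keep & mask, nrow(m), ncol(m))
}

#' Partition a section into medulla, CMJ, subcapsular band and cortex
#'
#' Given the medulla and whole-tissue masks, defines the
#' cortico-medullary junction (CMJ) as the band within `band_width_um`
#' outside the medulla, the subcapsular region as the band within
#' `band_width_um` inside the tissue perimeter, and the cortex as all
#' remaining tissue. Both bands are computed with Euclidean distance
#' transforms. Precedence where bands would overlap (thin tissue) is
#' medulla > CMJ > subcapsular > cortex, so the four region masks are
#' pairwise disjoint and together tile the tissue exactly.
#'
#' @param medulla Logical medulla mask (must lie inside `tissue`).
#' @param tissue Logical whole-tissue mask.
#' @param band_width_um Width of the CMJ and subcapsular bands (default
#'   100 micrometres).
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `region_partition`: logical masks
#'   `medulla`, `cmj`, `subcapsular`, `cortex`, `tissue`, plus
#'   `areas_um2` (named areas) and `band_width_um`.
#' @export
partition_regions <- function(medulla, tissue, band_width_um = 100,
                              pixel_size_um) {
  stopifnot(is.logical(medulla) || all(medulla %in% c(0, 1)),
            identical(dim(medulla), dim(tissue)))
  medulla <- medulla & TRUE; tissue <- tissue & TRUE
  if (any(medulla & !tissue))
    stop("medulla mask extends outside the tissue mask")
  band_px <- band_width_um / pixel_size_um
  if (any(medulla)) {
    d_med <- matrix(as.numeric(EBImage::distmap(as_ebi(1 - medulla))),
                    nrow(medulla), ncol(medulla))
  } else {
    d_med <- matrix(Inf, nrow(medulla), ncol(medulla))
  }
  d_in <- matrix(as.numeric(EBImage::distmap(as_ebi(tissue * 1))),
                 nrow(tissue), ncol(tissue))
  cmj <- tissue & !medulla & d_med <= band_px
  subcap <- tissue & !medulla & !cmj & d_in <= band_px
  cortex <- tissue & !medulla & !cmj & !subcap
  masks <- list(medulla = medulla, cmj = cmj, subcapsular = subcap,
                cortex = cortex, tissue = tissue)
  areas <- vapply(masks, function(m) sum(m) * pixel_size_um^2, numeric(1))
  structure(c(masks,
              list(areas_um2 = areas, band_width_um = band_width_um,
                   pixel_size_um = pixel_size_um)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> areas (um^2):\n")
  print(round(x$areas_um2))
  invisible(x)
}

#' Marker-positive cell density per thymic region
#'
#' Detects marker-positive objects by thresholding and connected
#' components with a minimum object area, assigns each object to a region
#' by the position of its centroid, and reports objects per square
#' micrometre. Counts are conserved: every detected object whose centroid
#' lies on tissue is counted in exactly one region. A zero-area region
#' reports a missing density rather than dividing by zero.
#'
#' @param channel [image_channel] of the cell marker (e.g. CD11c).
#' @param partition A [partition_regions] result.
#' @param threshold Either `"otsu"` or a numeric intensity cutoff on the
#'   normalized (0-1) channel.
#' @param min_area_um2 Minimum object area.
#' @return Data frame with columns `region`, `area_um2`, `count`,
#'   `density_per_um2`.
#' @export
cell_density <- function(channel, partition, threshold = "otsu",
                         min_area_um2 = 10) {
  stopifnot(inherits(channel, "image_channel"),
            inherits(partition, "region_partition"))
  m <- channel$intensities
  px <- channel$pixel_size_um
  rng <- range(m)
  regions <- c("medulla", "cmj", "subcapsular", "cortex")
  counts <- stats::setNames(integer(4), regions)
  if (rng[2] > rng[1]) {
    m01 <- (m - rng[1]) / (rng[2] - rng[1])
    thr <- if (identical(threshold, "otsu"))
      EBImage::otsu(as_ebi(m01)) else as.numeric(threshold)
    lab <- matrix(as.integer(EBImage::bwlabel(as_ebi(m01 > thr))),
                  nrow(m), ncol(m))
    if (max(lab) > 0L) {
      sizes <- tabulate(lab)
      min_px <- max(1L, floor(min_area_um2 / px^2))
      idx <- which(lab > 0L)
      obj <- lab[idx]
      rows <- ((idx - 1L) %% nrow(m)) + 1L
      cols <- ((idx - 1L) %/% nrow(m)) + 1L
      cr <- round(rowsum(rows, obj)[, 1] / sizes[sizes > 0])
      cc <- round(rowsum(cols, obj)[, 1] / sizes[sizes > 0])
      keep <- sizes[sizes > 0] >= min_px
      for (k in which(keep)) {
        pos <- cbind(cr[k], cc[k])
        for (rg in regions) {
          if (partition[[rg]][pos]) {
            counts[rg] <- counts[rg] + 1L
            break
          }
        }
      }
    }
  }
  areas <- partition$areas_um2[regions]
  data.frame(region = regions,
             area_um2 = as.numeric(areas),
             count = as.integer(counts),
             density_per_um2 = ifelse(areas > 0, counts / areas, NA_real_),
             row.names = NULL)
}
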