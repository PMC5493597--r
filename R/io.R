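read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop("unsupported image format '.", ext, "': ", path))
  img
}

#' Load a condition's images from a directory
#'
#' Two input conventions are supported. In `rgb` mode every TIFF/PNG in
#' the directory is an RGB composite whose red plane is channel A and
#' green plane channel B (a blue counterstain such as DAPI is ignored).
#' In `paired` mode each section is stored as two single-channel files
#' sharing a base name that differs only by a channel-identifier token
#' (default `_ch1` / `_ch2`, configurable — marker names such as `_K14` /
#' `_UEA1` work the same way). Files are paired by the remaining stem;
#' unmatched files are an error, listed by name. Sorted filename order
#' defines pair order, so loading is reproducible.
#'
#' Intensities are converted to floating point as read (0-1 for integer
#' TIFF/PNG); no normalization is applied — the analysis subtracts each
#' image's mean and works in log units, so overall gain shifts curves by
#' a constant without affecting comparisons.
#'
#' @param directory Directory containing the images.
#' @param mode `"rgb"` or `"paired"`.
#' @param pixel_size_um Physical pixel size of the images, micrometres.
#' @param channel_tokens Length-2 character vector of identifier tokens
#'   for paired mode.
#' @param label Condition label (defaults to the directory name).
#' @return A [condition_dataset].
#' @export
load_condition <- function(directory, mode = c("rgb", "paired"),
                           pixel_size_um,
                           channel_tokens = c("_ch1", "_ch2"),
                           label = basename(directory)) {
  mode <- match.arg(mode)
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  files <- sort(list.files(directory, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files))
    stop("no TIFF/PNG images found in ", directory)
  as_channel <- function(m) {
    if (any(m < 0)) stop("negative intensities in loaded image")
    image_channel(m, pixel_size_um)
  }
  if (mode == "rgb") {
    pairs <- lapply(files, function(f) {
      img <- read_image_file(f)
      if (length(dim(img)) != 3L || dim(img)[3] < 2L)
        stop("not an RGB image (need >= 2 planes): ", f)
      list(a = as_channel(img[, , 1]), b = as_channel(img[, , 2]))
    })
    return(condition_dataset(pairs, label = label))
  }
  stopifnot(length(channel_tokens) == 2L)
  base <- basename(files)
  stem <- tools::file_path_sans_ext(base)
  has1 <- grepl(channel_tokens[1], stem, fixed = TRUE)
  has2 <- grepl(channel_tokens[2], stem, fixed = TRUE)
  orphan <- files[!(has1 | has2)]
  key <- stem
  key[has1] <- sub(channel_tokens[1], "", stem[has1], fixed = TRUE)
  key[has2] <- sub(channel_tokens[2], "", stem[has2], fixed = TRUE)
  keys <- sort(unique(key[has1 | has2]))
  pairs <- list()
  for (k in keys) {
    f1 <- files[has1 & key == k]
    f2 <- files[has2 & key == k]
    if (length(f1) != 1L || length(f2) != 1L) {
      orphan <- c(orphan, f1, f2)
      next
    }
    m1 <- read_image_file(f1); m2 <- read_image_file(f2)
    if (length(dim(m1)) == 3L) m1 <- m1[, , 1]
    if (length(dim(m2)) == 3L) m2 <- m2[, , 1]
    if (!identical(dim(m1), dim(m2)))
      stop("pair '", k, "': channel shapes differ (",
           paste(dim(m1), collapse = "x"), " vs ",
           paste(dim(m2), collapse = "x"), ")")
    pairs[[length(pairs) + 1L]] <- list(a = as_channel(m1),
                                        b = as_channel(m2))
  }
  if (length(orphan))
    stop("unpaired files in ", directory, ": ",
         paste(basename(orphan), collapse = ", "))
  if (!length(pairs)) stop("no image pairs found in ", directory)
  condition_dataset(pairs, label = label)
}

curve_to_frame <- function(ci) {
  data.frame(frequency_cyc_per_um = ci$grid$frequencies,
             length_scale_um = 1 / ci$grid$frequencies,
             estimate = ci$estimate,
             ci_lower = ci$ci_lower,
             ci_upper = ci$ci_upper)
}

#' Write the six output curves of an analysis to CSV files
#'
#' One CSV per curve (named after the curve, e.g. `log_spectrum_a.csv`)
#' with columns `frequency_cyc_per_um`, `length_scale_um` (= 1/frequency),
#' `estimate`, `ci_lower`, `ci_upper`. One row per radial bin; masked
#' bins have empty value fields. Values are written with 12 significant
#' digits, so re-reading reproduces the curves to that precision.
#'
#' @param result A [micasa_analyze] result.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_radial_csv <- function(result, directory) {
  stopifnot(inherits(result, "micasa_result"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in result_curve_names) {
    df <- curve_to_frame(result[[nm]])
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x)
      ifelse(is.na(x), "", sprintf("%.12g", x)))
    p <- file.path(directory, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("micasa")),
                   label = result$label, N = result$N, M = result$M,
                   NM = result$NM, config = unclass(result$config))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Re-read an analysis written by [write_radial_csv]
#'
#' Reconstructs a `micasa_result` (curves and metadata) from the CSV
#' files and JSON manifest of an output directory, enabling comparisons
#' between separately run analyses.
#'
#' @param directory Directory written by [write_radial_csv].
#' @return A `micasa_result`.
#' @export
read_radial_result <- function(directory) {
  man <- jsonlite::read_json(file.path(directory, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(analysis_config, man$config)
  out <- list(N = man$N, M = man$M, NM = man$NM, label = man$label,
              config = cfg)
  grid <- NULL
  for (nm in result_curve_names) {
    df <- utils::read.csv(file.path(directory, paste0(nm, ".csv")))
    if (is.null(grid)) {
      f <- df$frequency_cyc_per_um
      # recover log-spaced edges from centres
      step <- mean(diff(log(f)))
      edges <- exp(c(log(f) - step / 2, log(f[length(f)]) + step / 2))
      grid <- structure(list(frequencies = f, bin_edges = edges),
                        class = "radial_grid")
    }
    out[[nm]] <- ci_function(grid, df$estimate, df$ci_lower, df$ci_upper,
                             cfg$confidence_level, man$NM - 1,
                             mask = !is.finite(df$estimate))
  }
  out$grid <- grid
  structure(out, class = "micasa_result")
}

length_scale_ticks <- function(f_range) {
  scales <- sort(unique(c(1, 2, 4) %o% 10^(-1:5)))
  f <- 1 / scales
  keep <- f >= f_range[1] & f <= f_range[2]
  list(at = f[keep], labels = formatC(scales[keep], format = "fg"))
}

draw_band <- function(ci, col, border) {
  ok <- !ci$mask
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  for (j in which(runs$values)) {
    idx <- starts[j]:ends[j]
    f <- ci$grid$frequencies[idx]
    graphics::polygon(c(f, rev(f)),
                      c(ci$ci_lower[idx], rev(ci$ci_upper[idx])),
                      col = col, border = NA)
    graphics::lines(f, ci$estimate[idx], col = border, lwd = 1)
  }
}

#' Plot the six output curves with confidence bands
#'
#' Draws each curve against log spatial frequency, with the abscissa
#' labelled by the corresponding length scale in micrometres (so a tick
#' at frequency 1/400 reads "400"). Confidence intervals are drawn as
#' shaded bands whose vertical extent spans `[ci_lower, ci_upper]`; a
#' second result can be overlaid in a contrasting colour so that
#' non-overlapping bands identify significant differences directly on the
#' figure. When `path` ends in `.pdf` or `.png` the figure is written to
#' file; with `path = NULL` it draws on the current device.
#'
#' @param result A `micasa_result`.
#' @param path Output file (`.pdf` or `.png`) or NULL.
#' @param compare Optional second `micasa_result` to overlay.
#' @param width,height Device size in inches.
#' @return Invisibly, `path`.
#' @export
plot_result <- function(result, path = NULL, compare = NULL,
                        width = 10, height = 6) {
  stopifnot(inherits(result, "micasa_result"))
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
      "pdf" = grDevices::pdf(path, width = width, height = height),
      "png" = grDevices::png(path, width = width * 100,
                             height = height * 100, res = 100),
      stop("unsupported plot format '.", ext, "'"))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(2, 3), mar = c(4.5, 4, 2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  cols <- list(c(grDevices::adjustcolor("darkgreen", 0.35), "darkgreen"),
               c(grDevices::adjustcolor("grey30", 0.35), "grey30"))
  for (nm in result_curve_names) {
    cis <- list(result[[nm]])
    if (!is.null(compare)) cis <- c(cis, list(interp_ci(compare[[nm]],
                                                        result$grid)))
    ok <- unlist(lapply(cis, function(ci) !ci$mask))
    ylim <- range(unlist(lapply(cis, function(ci)
      c(ci$ci_lower[!ci$mask], ci$ci_upper[!ci$mask]))), finite = TRUE)
    f_ok <- result$grid$frequencies[!cis[[1]]$mask]
    graphics::plot(NA, xlim = range(f_ok), ylim = ylim, log = "x",
                   xaxt = "n", xlab = "length scale (um)", ylab = nm,
                   main = nm, cex.main = 0.9)
    tk <- length_scale_ticks(range(f_ok))
    graphics::axis(1, at = tk$at, labels = tk$labels)
    for (k in seq_along(cis))
      draw_band(cis[[k]], cols[[k]][1], cols[[k]][2])
  }
  invisible(path)
}
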