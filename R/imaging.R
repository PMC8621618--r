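#' Section image container
#'
#' A rendered (or read) multichannel section: `height x width x 6` pixel
#' array, channels in digit order (1 YFP, 2 mKO, 3 mCerulean, 4 mCherry,
#' 5 mT-Sapphire, 6 EGFP), plus the rendering geometry needed to quantify
#' it back.
#'
#' @param pixels Numeric array `height x width x 6`, non-negative.
#' @param pixel_size Pixel size in microns per pixel.
#' @param nucleus_radius,cell_radius Disk radii (pixels) of the nucleus and
#'   the cytoplasm outer edge; `0 < nucleus_radius < cell_radius`.
#' @return Object of class `section_image`.
#' @export
section_image <- function(pixels, pixel_size = 1, nucleus_radius = 4,
                          cell_radius = 9) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 6L) {
    abort("`pixels` must be a height x width x 6 array.")
  }
  if (any(pixels < 0)) abort("pixel intensities must be non-negative.")
  if (!(nucleus_radius > 0 && cell_radius > nucleus_radius)) {
    abort("need 0 < nucleus_radius < cell_radius.")
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         nucleus_radius = nucleus_radius, cell_radius = cell_radius),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<section_image> ", d[1], " x ", d[2], " px, 6 channels, ",
      x$pixel_size, " um/px\n", sep = "")
  invisible(x)
}

# disk / annulus pixel masks around an integer-ish center, as index matrix
compartment_masks <- function(x, y, nucleus_radius, cell_radius, height, width) {
  r <- ceiling(cell_radius)
  rows <- max(1L, floor(y - r)):min(height, ceiling(y + r))
  cols <- max(1L, floor(x - r)):min(width, ceiling(x + r))
  d2 <- outer((rows - y)^2, (cols - x)^2, "+")
  idx <- function(mask) {
    cbind(row = rep(rows, times = length(cols))[mask],
          col = rep(cols, each = length(rows))[mask])
  }
  list(
    nucleus = idx(as.vector(d2 <= nucleus_radius^2)),
    cytoplasm = idx(as.vector(d2 > nucleus_radius^2 & d2 <= cell_radius^2))
  )
}

#' Render a synthetic multichannel section image
#'
#' Forward model for the quantification stage: each cell is drawn as a
#' nucleus disk carrying its six nuclear intensities and a surrounding
#' cytoplasm annulus carrying its six cytoplasmic intensities, added on top
#' of a flat background, with optional additive Gaussian pixel noise.
#'
#' @param cells Cell-table rows for one section, with `x`, `y` pixel
#'   coordinates and the 12 intensity columns.
#' @param width,height Image size in pixels.
#' @param nucleus_radius,cell_radius Cell geometry in pixels.
#' @param background_level Flat background intensity.
#' @param noise_sd SD of additive Gaussian pixel noise (0 = noiseless).
#' @param allow_overlap Permit overlapping cells (their intensities add)?
#'   Default `FALSE`: overlapping centers are an error.
#' @return A [section_image()].
#' @export
render_section <- function(cells, width = 512L, height = 512L,
                           nucleus_radius = 4, cell_radius = 9,
                           background_level = 5, noise_sd = 0,
                           allow_overlap = FALSE) {
  img <- array(background_level, dim = c(height, width, 6L))
  n <- nrow(cells)
  if (n > 0L) {
    if (any(cells$x < cell_radius + 1 | cells$x > width - cell_radius |
            cells$y < cell_radius + 1 | cells$y > height - cell_radius)) {
      abort("cell coordinates out of image bounds (closer than cell_radius to an edge).")
    }
    if (!allow_overlap && n > 1L) {
      d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
      diag(d) <- Inf
      if (min(d) <= 2 * cell_radius) {
        abort("cells overlap; set allow_overlap = TRUE to permit it.")
      }
    }
    cyt_cols <- paste0(XFP_NAMES, "_cyt")
    nuc_cols <- paste0(XFP_NAMES, "_nuc")
    for (i in seq_len(n)) {
      masks <- compartment_masks(cells$x[i], cells$y[i],
                                 nucleus_radius, cell_radius, height, width)
      for (ch in 1:6) {
        img[cbind(masks$nucleus, ch)] <-
          img[cbind(masks$nucleus, ch)] + cells[[nuc_cols[ch]]][i]
        img[cbind(masks$cytoplasm, ch)] <-
          img[cbind(masks$cytoplasm, ch)] + cells[[cyt_cols[ch]]][i]
      }
    }
  }
  if (noise_sd > 0) {
    img <- pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
  }
  section_image(img, nucleus_radius = nucleus_radius,
                cell_radius = cell_radius)
}

#' Detect labeled cells in a section image
#'
#' Blob detection on the across-channel maximum projection (so cells
#' labeled in a single channel are not missed): pixels brighter than the
#' per-image median background by `min_intensity` are segmented into
#' connected components; components of at least `min_area` pixels yield one
#' centroid each.
#'
#' @param image A [section_image()].
#' @param min_intensity Threshold above the median background.
#' @param min_area Minimum component area in pixels.
#' @return Tibble of centroids with `x`, `y` (pixels) and `area`; zero rows
#'   on a blank image.
#' @export
detect_cells <- function(image, min_intensity = 20, min_area = 12) {
  stopifnot(inherits(image, "section_image"))
  proj <- image$pixels[, , 1L]
  for (ch in 2:6) proj <- pmax(proj, image$pixels[, , ch])
  bg <- stats::median(proj)
  mask <- proj > bg + min_intensity
  if (!any(mask)) {
    return(tibble::tibble(x = numeric(), y = numeric(), area = integer()))
  }
  lab <- EBImage::bwlabel(mask)
  on <- lab > 0
  labs <- lab[on]
  rows <- row(lab)[on]
  cols <- col(lab)[on]
  area <- tabulate(labs)
  cx <- tapply(cols, labs, mean)
  cy <- tapply(rows, labs, mean)
  keep <- area >= min_area
  tibble::tibble(
    x = as.numeric(cx)[keep],
    y = as.numeric(cy)[keep],
    area = area[keep]
  )
}

#' Quantify per-cell compartment intensities from a section image
#'
#' For each centroid, the nuclear value of a channel is the mean over the
#' nucleus disk and the cytoplasmic value the mean over the cytoplasm
#' annulus, both background-subtracted (background = per-channel image
#' median, a robust, parameter-free estimate). Centroids too close to the
#' image border are flagged rather than silently cropped.
#'
#' @param image A [section_image()].
#' @param centroids Tibble with `x`, `y` (e.g. from [detect_cells()]).
#' @param nucleus_radius,cell_radius Optional geometry override; defaults
#'   to the image's own.
#' @return Tibble with `x`, `y`, `border` (flag) and the 12 intensity
#'   columns; intensities are `NA` for border-flagged cells.
#' @export
quantify_cells <- function(image, centroids, nucleus_radius = NULL,
                           cell_radius = NULL) {
  stopifnot(inherits(image, "section_image"))
  rn <- nucleus_radius %||% image$nucleus_radius
  rc <- cell_radius %||% image$cell_radius
  height <- dim(image$pixels)[1L]
  width <- dim(image$pixels)[2L]
  bg <- vapply(1:6, function(ch) stats::median(image$pixels[, , ch]),
               numeric(1))
  out <- matrix(NA_real_, nrow(centroids), 12L,
                dimnames = list(NULL, reporter_cols()))
  border <- centroids$x < rc + 1 | centroids$x > width - rc |
    centroids$y < rc + 1 | centroids$y > height - rc
  for (i in seq_len(nrow(centroids))) {
    if (border[i]) next
    masks <- compartment_masks(centroids$x[i], centroids$y[i],
                               rn, rc, height, width)
    for (ch in 1:6) {
      out[i, ch] <- mean(image$pixels[cbind(masks$cytoplasm, ch)]) - bg[ch]
      out[i, ch + 6L] <- mean(image$pixels[cbind(masks$nucleus, ch)]) - bg[ch]
    }
  }
  out <- pmax(out, 0)
  dplyr::bind_cols(
    tibble::tibble(x = centroids$x, y = centroids$y, border = border),
    tibble::as_tibble(out)
  )
}

#' Write a section image as multichannel TIFF
#'
#' One page per channel in digit order, 32-bit float, intensities divided
#' by `scale` to fit the unit range of the format.
#'
#' @param image A [section_image()].
#' @param path Output file path.
#' @param scale Intensity scale factor (use the same value when reading
#'   back).
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(image, path, scale = 4096) {
  stopifnot(inherits(image, "section_image"))
  pages <- lapply(1:6, function(ch) image$pixels[, , ch] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multichannel section TIFF written by [write_section_tiff()]
#'
#' @param path File path.
#' @param scale Intensity scale factor used when writing.
#' @param pixel_size,nucleus_radius,cell_radius Geometry to attach.
#' @return A [section_image()].
#' @export
read_section_tiff <- function(path, scale = 4096, pixel_size = 1,
                              nucleus_radius = 4, cell_radius = 9) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 6L) {
    abort(sprintf("expected 6 channel pages, found %d.", length(pages)))
  }
  img <- array(0, dim = c(dim(pages[[1L]]), 6L))
  for (ch in 1:6) img[, , ch] <- pages[[ch]] * scale
  section_image(img, pixel_size = pixel_size,
                nucleus_radius = nucleus_radius, cell_radius = cell_radius)
}
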