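#' Construct a z-stack
#'
#' @param voxels 3D numeric array, `y by x by z` (or a 2D matrix for a
#'   single slice), non-negative intensities.
#' @param pixel_um lateral pixel size, um/px (> 0).
#' @param z_step_um z interval, um. Default 0.5, the usual confocal
#'   stack spacing for this kind of material.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_um, z_step_um = 0.5) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3) stopf("voxels must be a 2D or 3D array")
  if (any(voxels < 0)) stopf("intensities must be non-negative")
  if (!is_number(pixel_um) || pixel_um <= 0) stopf("pixel_um must be > 0")
  structure(list(voxels = voxels, pixel_um = pixel_um,
                 z_step_um = z_step_um),
            class = "image_stack")
}

#' Sum projection of a z-stack
#'
#' Projects a stack to a single image by per-pixel summation across z,
#' preserving total (integrated) intensity, which is what the downstream
#' punctum photometry measures.
#'
#' @param stack an [image_stack()] (or a plain 3D array with a `pixel_um`
#'   attribute).
#' @return projection matrix with attribute `pixel_um`.
#' @export
zproject_sum <- function(stack) {
  if (inherits(stack, "image_stack")) {
    v <- stack$voxels; px <- stack$pixel_um
  } else {
    v <- stack; px <- attr(stack, "pixel_um")
    if (is.matrix(v)) dim(v) <- c(dim(v), 1L)
  }
  if (dim(v)[3] < 1) stopf("stack must contain at least one slice")
  out <- rowSums(v, dims = 2)
  attr(out, "pixel_um") <- px
  out
}

#' Li minimum-cross-entropy threshold
#'
#' Returns the intensity threshold minimising Li's cross-entropy between
#' the image and its binarised version, computed over a histogram of the
#' image (256 bins by default for float data). Writing `S_b`, `S_f` for
#' the intensity mass and `mu_b`, `mu_f` for the mean intensity below and
#' above a candidate threshold, the criterion minimised is
#' `-(S_b log mu_b + S_f log mu_f)`; the minimiser is found by exhaustive
#' search over all histogram cut points, which is exact on the binned
#' histogram. Intensities are shifted to positive values internally when
#' the image contains non-positive pixels (the criterion needs positive
#' support); the returned threshold is on the original scale.
#'
#' @param image numeric matrix.
#' @param n_bins number of histogram bins. Default 256.
#' @return threshold value. A constant image is flagged degenerate: the
#'   constant is returned with a warning.
#' @export
li_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) == 0) stopf("empty image")
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    warnf("constant image: Li threshold degenerate")
    return(lo)
  }
  bin_w <- (hi - lo) / n_bins
  shift <- if (lo <= 0) -lo + bin_w else 0
  v <- v + shift
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  mid <- h$mids
  cum_n <- cumsum(cnt)
  cum_s <- cumsum(cnt * mid)
  n_tot <- cum_n[n_bins]
  s_tot <- cum_s[n_bins]
  best <- Inf
  best_cut <- NA_real_
  for (i in seq_len(n_bins - 1)) {
    nb <- cum_n[i]; nf <- n_tot - nb
    if (nb == 0 || nf == 0) next
    sb <- cum_s[i]; sf <- s_tot - sb
    obj <- -(sb * log(sb / nb) + sf * log(sf / nf))
    if (obj < best) {
      best <- obj
      best_cut <- h$breaks[i + 1]
    }
  }
  best_cut - shift
}

#' FFT band-pass filter
#'
#' Frequency-domain difference-of-Gaussians filter used to enhance
#' punctate contrast before segmentation: structure smaller than
#' `small_px` and larger than `large_px` is suppressed, and the DC
#' component is removed entirely. The transfer function at spatial
#' frequency `f` (cycles/px) is [bandpass_transfer()]:
#' `H(f) = exp(-2 pi^2 (small_px/2)^2 f^2) - exp(-2 pi^2 (large_px/2)^2 f^2)`,
#' i.e. Gaussian smoothing kernels of spatial sigma `small_px / 2` and
#' `large_px / 2`. The operator is linear.
#'
#' @param image numeric matrix (attributes such as `pixel_um` preserved).
#' @param small_px suppress structure smaller than this size, px (> 0).
#' @param large_px suppress structure larger than this size, px
#'   (> `small_px`).
#' @return filtered matrix.
#' @export
fft_bandpass <- function(image, small_px = 1, large_px = 8) {
  if (!is_number(small_px) || small_px <= 0 ||
      !is_number(large_px) || large_px <= small_px)
    stopf("need large_px > small_px > 0")
  nr <- nrow(image); nc <- ncol(image)
  fr <- fft_freq(nr); fc <- fft_freq(nc)
  f2 <- outer(fr^2, fc^2, `+`)
  H <- bandpass_transfer(sqrt(f2), small_px, large_px)
  out <- Re(fft(fft(image) * H, inverse = TRUE)) / (nr * nc)
  attributes(out) <- attributes(image)
  out
}

#' @rdname fft_bandpass
#' @param f spatial frequency in cycles per pixel.
#' @export
bandpass_transfer <- function(f, small_px, large_px) {
  exp(-2 * pi^2 * (small_px / 2)^2 * f^2) -
    exp(-2 * pi^2 * (large_px / 2)^2 * f^2)
}

fft_freq <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))
  (k / n)[seq_len(n)]
}

#' H-watershed segmentation of fluorescent puncta
#'
#' Splits adjacent puncta by watershed with an `h` seed dynamic: local
#' maxima count as seeds only when they exceed their surroundings by at
#' least `h`, so shallow intensity ripples do not fragment a punctum while
#' a genuine doublet with a valley deeper than `h` is split in two.
#' Watershed runs on the intensity image restricted to the supra-threshold
#' mask; the mask threshold defaults to [li_threshold()] of the image.
#'
#' @param image numeric matrix (typically the band-passed projection).
#' @param h seed dynamic (> 0); default 10% of the supra-threshold dynamic
#'   range `max(image) - mask_threshold`.
#' @param mask_threshold intensity cut defining foreground; default
#'   `li_threshold(image)`.
#' @return integer label matrix (0 = background), one label per punctum.
#'   An empty mask yields an all-zero labelling with a message.
#' @export
hwatershed_segment <- function(image, h = NULL, mask_threshold = NULL) {
  if (is.null(mask_threshold)) mask_threshold <- li_threshold(image)
  mask <- image > mask_threshold
  if (!any(mask)) {
    message("empty foreground mask: no puncta segmented")
    out <- matrix(0L, nrow(image), ncol(image))
    attr(out, "pixel_um") <- attr(image, "pixel_um")
    return(out)
  }
  if (is.null(h)) h <- 0.1 * (max(image) - mask_threshold)
  if (!is_number(h) || h <= 0) stopf("h must be > 0")
  rel <- (image - mask_threshold) * mask
  w <- EBImage::watershed(EBImage::Image(rel), tolerance = h, ext = 1)
  out <- matrix(as.integer(EBImage::imageData(w)), nrow(image), ncol(image))
  attr(out, "pixel_um") <- attr(image, "pixel_um")
  out
}

#' Particle analysis: area filtering and background-subtracted photometry
#'
#' Converts each label's pixel count to um^2 and keeps particles within
#' `[area_min_um2, area_max_um2]` (0.05-1 um^2 by default, bracketing the
#' ~178 nm diffraction-limited punctum size). The integrated intensity of
#' a particle is the sum of `pixel - background` over its pixels, measured
#' on `image` -- normally the unfiltered sum projection, so photometry is
#' not biased by the band-pass. Background defaults to the median of
#' pixels outside all labels.
#'
#' @param labels integer label matrix from [hwatershed_segment()].
#' @param image measurement image (same dimensions).
#' @param pixel_um um/px; taken from the `pixel_um` attribute of `labels`
#'   or `image` when missing.
#' @param area_min_um2,area_max_um2 area acceptance window, um^2.
#' @param background scalar background level; default
#'   `median(image[labels == 0])`.
#' @return data frame of class `punctum_set`: `label`, `area_um2`,
#'   `intensity` (background-subtracted integrated), `x_px`, `y_px`
#'   (0-based centroids); attributes `pixel_um`, `background`.
#' @export
particle_analysis <- function(labels, image, pixel_um = NULL,
                              area_min_um2 = 0.05, area_max_um2 = 1.0,
                              background = NULL) {
  if (!all(dim(labels) == dim(image)))
    stopf("labels and image dimensions differ")
  pixel_um <- pixel_um %||% attr(labels, "pixel_um") %||%
    attr(image, "pixel_um")
  if (is.null(pixel_um)) stopf("pixel_um is required (flag or image metadata)")
  lab <- as.integer(labels)
  img <- as.numeric(image)
  if (is.null(background)) {
    bg_px <- img[lab == 0L]
    background <- if (length(bg_px) > 0) median(bg_px) else 0
  }
  n_lab <- max(lab, 0L)
  if (n_lab == 0L) return(empty_punctum_set(pixel_um, background))
  npx <- tabulate(lab, nbins = n_lab)
  area <- npx * pixel_um^2
  keep <- which(npx > 0 & area >= area_min_um2 & area <= area_max_um2)
  if (length(keep) == 0) return(empty_punctum_set(pixel_um, background))
  sums <- rowsum(img[lab > 0L], lab[lab > 0L])
  ids <- as.integer(rownames(sums))
  sum_by <- setNames(sums[, 1], ids)
  idx <- which(lab > 0L)
  rc <- cbind((idx - 1L) %% nrow(image), (idx - 1L) %/% nrow(image))
  cx <- rowsum(rc[, 1], lab[idx])[, 1]
  cy <- rowsum(rc[, 2], lab[idx])[, 1]
  out <- data.frame(
    label = keep,
    area_um2 = area[keep],
    intensity = sum_by[as.character(keep)] - background * npx[keep],
    x_px = cx[as.character(keep)] / npx[keep],
    y_px = cy[as.character(keep)] / npx[keep])
  rownames(out) <- NULL
  class(out) <- c("punctum_set", "data.frame")
  attr(out, "pixel_um") <- pixel_um
  attr(out, "background") <- background
  out
}

empty_punctum_set <- function(pixel_um, background) {
  out <- data.frame(label = integer(0), area_um2 = numeric(0),
                    intensity = numeric(0), x_px = numeric(0),
                    y_px = numeric(0))
  class(out) <- c("punctum_set", "data.frame")
  attr(out, "pixel_um") <- pixel_um
  attr(out, "background") <- background
  out
}
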