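#' Full punctum quantification pipeline
#'
#' Runs the image-processing chain on a z-stack or single image: sum
#' projection, Li threshold, FFT band-pass, h-watershed segmentation and
#' particle analysis. By default the watershed mask is recomputed by Li
#' thresholding the band-passed image (thresholding after background
#' suppression is better-posed); `strict_order = TRUE` instead applies the
#' threshold computed on the raw projection. Photometry is always measured
#' on the unfiltered projection.
#'
#' @param stack an [image_stack()], a `synthetic_field`, or a matrix with a
#'   `pixel_um` attribute.
#' @param pixel_um um/px override.
#' @param small_px band-pass small-structure cut, px. Default 1.
#' @param large_px band-pass large-structure cut, px; default four times
#'   the PSF full width at half maximum (derived from `psf_fwhm_um`).
#' @param psf_fwhm_um assumed PSF FWHM used for the `large_px` default;
#'   default 0.178 um (488 nm / NA 1.4).
#' @param h watershed seed dynamic; `NULL` uses 10% of the supra-threshold
#'   dynamic range.
#' @param area_min_um2,area_max_um2 particle-area acceptance window.
#' @param strict_order use the raw-projection Li threshold for the mask.
#' @return list of class `puncta_quant`: `puncta` (a `punctum_set`),
#'   `labels`, `projection`, `filtered`, `threshold`, `h`.
#' @export
quantify_puncta <- function(stack, pixel_um = NULL, small_px = 1,
                            large_px = NULL, psf_fwhm_um = 0.178, h = NULL,
                            area_min_um2 = 0.05, area_max_um2 = 1.0,
                            strict_order = FALSE) {
  img <- if (inherits(stack, "synthetic_field")) stack$image
         else if (inherits(stack, "image_stack")) zproject_sum(stack)
         else if (is.matrix(stack) && !is.null(dim(stack))) stack
         else stopf("unsupported input for quantify_puncta")
  pixel_um <- pixel_um %||% attr(img, "pixel_um")
  if (is.null(pixel_um)) stopf("pixel_um is required")
  if (is.null(large_px)) large_px <- 4 * psf_fwhm_um / pixel_um

  thr_raw <- li_threshold(img)
  filt <- fft_bandpass(img, small_px = small_px, large_px = large_px)
  thr <- if (strict_order) thr_raw else li_threshold(filt)
  labels <- hwatershed_segment(filt, h = h, mask_threshold = thr)
  puncta <- particle_analysis(labels, img, pixel_um = pixel_um,
                              area_min_um2 = area_min_um2,
                              area_max_um2 = area_max_um2)
  structure(list(puncta = puncta, labels = labels, projection = img,
                 filtered = filt, threshold = thr,
                 h = h %||% 0.1 * (max(filt) - thr)),
            class = "puncta_quant")
}

#' @export
print.puncta_quant <- function(x, ...) {
  cat(sprintf("Punctum quantification: %d puncta (mask threshold %.4g)\n",
              nrow(x$puncta), x$threshold))
  invisible(x)
}

#' Rank-order intensity scaling between two punctum sets
#'
#' Filters each set to particles no larger than its Mean+3SD single-punctum
#' area cutoff (from [fit_area_gaussian()] unless supplied), equalises the
#' two counts by seeded random subsampling, ranks the integrated
#' intensities from smallest to largest, and fits the scaling factor over
#' the lowest `fit_fraction` of ranks (0-90% by convention, because the
#' brightest puncta deviate from linearity).
#'
#' @param set_a,set_b `punctum_set` data frames (condition A = control on
#'   the x axis, condition B = treated on the y axis).
#' @param area_cutoffs length-2 numeric of area cutoffs (um^2) for the two
#'   sets; `NULL` fits each set's area histogram.
#' @param fit_fraction fraction of lowest ranks fitted. Default 0.9.
#' @param seed optional integer seed for count matching.
#' @param apply_cutoff set to `FALSE` to rank all puncta regardless of the
#'   area classification.
#' @return a [fit_scaling_factor()] result, with the cutoffs used attached
#'   as attribute `area_cutoffs`.
#' @export
puncta_scaling <- function(set_a, set_b, area_cutoffs = NULL,
                           fit_fraction = 0.9, seed = NULL,
                           apply_cutoff = TRUE) {
  stopifnot(is.data.frame(set_a), is.data.frame(set_b))
  if (apply_cutoff) {
    if (is.null(area_cutoffs))
      area_cutoffs <- c(fit_area_gaussian(set_a$area_um2)$cutoff,
                        fit_area_gaussian(set_b$area_um2)$cutoff)
    a <- set_a$intensity[set_a$area_um2 <= area_cutoffs[1]]
    b <- set_b$intensity[set_b$area_um2 <= area_cutoffs[2]]
  } else {
    area_cutoffs <- c(Inf, Inf)
    a <- set_a$intensity
    b <- set_b$intensity
  }
  if (length(a) == 0 || length(b) == 0)
    stopf("no puncta left after area-cutoff filtering")
  pairs <- build_rank_order(a, b, exclude_top = 0, seed = seed)
  fit <- fit_scaling_factor(pairs, fit_fraction = fit_fraction)
  attr(fit, "area_cutoffs") <- area_cutoffs
  fit
}

#' Standardised immunoreactivity ratio against a covariate
#'
#' Forms the background-subtracted ratio of two immunoreactivity (IR)
#' channels per region of interest (e.g. phospho-signal over a volume
#' marker), z-standardises both the ratio and a covariate IR to mean 0 /
#' SD 1, and reports their Pearson correlation. Regions whose denominator
#' is not positive after background subtraction are excluded with a count.
#'
#' @param numerator_ir,denominator_ir,covariate_ir equal-length numeric
#'   vectors of per-ROI immunoreactivities.
#' @param background scalar (or per-channel length-2 vector: numerator,
#'   denominator) background level subtracted before the ratio.
#' @return list: `ratio_z`, `covariate_z` (standardised vectors),
#'   `correlation`, `n`, `n_excluded`.
#' @export
standardize_ir <- function(numerator_ir, denominator_ir, covariate_ir,
                           background = 0) {
  n <- length(numerator_ir)
  if (length(denominator_ir) != n || length(covariate_ir) != n)
    stopf("all three IR vectors must have equal length")
  bg <- if (length(background) == 1) rep(background, 2) else background
  num <- numerator_ir - bg[1]
  den <- denominator_ir - bg[2]
  ok <- is.finite(num) & is.finite(den) & is.finite(covariate_ir) & den > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(sprintf("standardize_ir: excluded %d ROI(s) with non-positive denominator",
                    n_excluded))
  if (sum(ok) < 3) stopf("fewer than 3 usable ROIs")
  ratio <- num[ok] / den[ok]
  z <- function(x) (x - mean(x)) / sd(x)
  ratio_z <- z(ratio)
  cov_z <- z(covariate_ir[ok])
  list(ratio_z = ratio_z, covariate_z = cov_z,
       correlation = cor(ratio_z, cov_z), n = sum(ok),
       n_excluded = n_excluded)
}
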