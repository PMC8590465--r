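test_that("sum projection is the per-pixel sum across slices", {
  withr::with_seed(2, {
    slice <- matrix(runif(400, 0, 100), 20, 20)
    stack3 <- array(runif(20 * 20 * 5, 0, 100), dim = c(20, 20, 5))
  })
  one <- zproject_sum(image_stack(slice, pixel_um = 0.1))
  expect_equal(unclass(one)[, ], slice, ignore_attr = TRUE)
  expect_equal(attr(one, "pixel_um"), 0.1)

  two <- zproject_sum(image_stack(array(rep(slice, 2),
                                        dim = c(20, 20, 2)),
                                  pixel_um = 0.1))
  expect_equal(unclass(two)[, ], 2 * slice, ignore_attr = TRUE)

  rnd <- zproject_sum(image_stack(stack3, pixel_um = 0.1))
  expect_equal(unclass(rnd)[, ], apply(stack3, c(1, 2), sum),
               ignore_attr = TRUE)
})

test_that("Li threshold minimises the cross-entropy criterion", {
  # separates a two-level image strictly between its modes
  withr::with_seed(4, {
    two_level <- matrix(10, 40, 40)
    two_level[sample(1600, 160)] <- 200
  })
  t2 <- li_threshold(two_level)
  expect_gt(t2, 10)
  expect_lt(t2, 200)

  # equals brute-force minimisation on random 8-bit images
  withr::with_seed(5, {
    for (i in 1:8) {
      img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
      expect_equal(li_threshold(img), li_threshold_bruteforce(img))
    }
  })

  # shift covariance up to one histogram bin
  withr::with_seed(6, {
    img <- matrix(c(rnorm(800, 20, 3), rnorm(224, 80, 10)), 32, 32)
  })
  bin_w <- diff(range(img)) / 256
  expect_lt(abs(li_threshold(img + 37.5) - (li_threshold(img) + 37.5)),
            bin_w + 1e-9)

  expect_warning(t_const <- li_threshold(matrix(7, 5, 5)), "degenerate")
  expect_equal(t_const, 7)
})

test_that("FFT band-pass removes DC, preserves pass-band sinusoids, is linear", {
  const <- matrix(42, 64, 64)
  filtered <- fft_bandpass(const, 1, 8)
  expect_lt(max(abs(filtered)), 1e-9)

  # sinusoid with period inside the pass band: analytic transfer value
  n <- 128
  period <- 8
  s <- matrix(sin(2 * pi * (1:n) / period), n, n)
  fs <- fft_bandpass(s, 1, 32)
  H <- bandpass_transfer(1 / period, 1, 32)
  expect_equal(max(abs(fs)), H, tolerance = 1e-6)

  # linearity to machine precision
  withr::with_seed(7, {
    X <- matrix(rnorm(64 * 64), 64, 64)
    Y <- matrix(rnorm(64 * 64), 64, 64)
  })
  lhs <- fft_bandpass(2.5 * X - 1.3 * Y, 2, 10)
  rhs <- 2.5 * fft_bandpass(X, 2, 10) - 1.3 * fft_bandpass(Y, 2, 10)
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(fft_bandpass(const, 0, 8), "small_px")
  expect_error(fft_bandpass(const, 4, 2), "small_px")
})

test_that("h-watershed separates resolvable doublets and not closer pairs", {
  sig <- 2.5
  # one isolated spot: one label
  one <- spot_matrix(64, cbind(32, 32), 4000, sig)
  lab1 <- hwatershed_segment(one, mask_threshold = 1)
  expect_equal(max(lab1), 1)

  # doublet at 1.5 FWHM separation: intensity valley, two labels
  d_far <- 1.5 * 2.355 * sig
  two <- spot_matrix(64, rbind(c(32 - d_far / 2, 32), c(32 + d_far / 2, 32)),
                     c(4000, 3000), sig)
  lab2 <- hwatershed_segment(two, h = 20, mask_threshold = 1)
  expect_equal(max(lab2), 2)

  # pair at 0.3 FWHM: no valley, a single label
  d_near <- 0.3 * 2.355 * sig
  close_pair <- spot_matrix(64, rbind(c(32 - d_near / 2, 32),
                                      c(32 + d_near / 2, 32)),
                            c(4000, 3000), sig)
  lab3 <- hwatershed_segment(close_pair, h = 20, mask_threshold = 1)
  expect_equal(max(lab3), 1)

  # empty mask: empty labelling, not an error
  expect_message(lab0 <- hwatershed_segment(matrix(1, 16, 16),
                                            mask_threshold = 5),
                 "empty")
  expect_true(all(lab0 == 0))
})

test_that("particle analysis filters by area and measures exact photometry", {
  # uniform rectangular label: intensity (v - b) * npx exactly
  img <- matrix(3, 40, 40)
  img[10:17, 10:19] <- 50
  lab <- matrix(0L, 40, 40)
  lab[10:17, 10:19] <- 1L
  ps <- particle_analysis(lab, img, pixel_um = 0.1, background = 3)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$intensity, (50 - 3) * 80)
  expect_equal(ps$area_um2, 80 * 0.1^2)
  expect_equal(ps$x_px, mean(9:16))

  # labels outside the area window are discarded
  lab2 <- lab
  lab2[30:31, 30] <- 2L   # 2 px = 0.02 um^2 < 0.05
  ps2 <- particle_analysis(lab2, img, pixel_um = 0.1, background = 3)
  expect_equal(ps2$label, 1L)

  too_big <- matrix(1L, 40, 40) # 16 um^2 > 1
  expect_equal(nrow(particle_analysis(too_big, img, pixel_um = 0.1)), 0)

  expect_error(particle_analysis(lab, img), "pixel_um")
  expect_error(particle_analysis(lab, matrix(0, 4, 4), pixel_um = 0.1),
               "dimensions")

  # noiseless synthetic puncta: measured intensity within 2% of truth
  m <- puncta_field_model(field_um = c(10, 10), density = 0.08,
                          gain = 0, read_sd = 0, background_level = 0,
                          doublet_fraction = 0, intensity_sigma_log = 0)
  f <- synth_puncta_image(m, seed = 12)
  expect_gt(nrow(f$truth), 0)
  labf <- hwatershed_segment(f$image, mask_threshold = 1e-4)
  psf <- particle_analysis(labf, f$image, pixel_um = m$pixel_um,
                           background = 0, area_max_um2 = 5)
  expect_equal(nrow(psf), nrow(f$truth))
  # match truth to measured labels by centroid; the 2% photometry bound
  # applies away from the field border (edge spots lose tail mass)
  border <- pmin(f$truth$x_um, f$truth$y_um,
                 m$field_um[1] - f$truth$x_um, m$field_um[2] - f$truth$y_um)
  for (i in which(border > 5 * m$spot_sigma_um)) {
    j <- which.min((psf$x_px * m$pixel_um - f$truth$x_um[i])^2 +
                     (psf$y_px * m$pixel_um - f$truth$y_um[i])^2)
    expect_lt(abs(psf$intensity[j] - f$truth$intensity[i]) /
                f$truth$intensity[i], 0.02)
  }
  expect_gt(sum(border > 5 * m$spot_sigma_um), 0)
})

test_that("area histogram fit recovers Gaussian parameters and the cutoff", {
  withr::with_seed(13, areas <- rnorm(4000, 0.12, 0.03))
  fit <- fit_area_gaussian(areas)
  expect_lt(abs(fit$mu_area - 0.12) / 0.12, 0.03)
  expect_lt(abs(fit$cutoff - (0.12 + 3 * 0.03)) / (0.12 + 3 * 0.03), 0.05)
  # cross-check against direct moment estimates
  expect_lt(abs(fit$mu_area - mean(areas)), 0.01)
  expect_lt(abs(fit$sigma_area - sd(areas)), 0.01)
  expect_gt(fit$cutoff, fit$mu_area)

  expect_error(fit_area_gaussian(rep(0.1, 100)), "identical")
  expect_error(fit_area_gaussian(rnorm(20, 0.1, 0.02)), "at least 50")

  # report style mirrors the conventional mean + 3 SD phrasing
  out <- capture.output(print(fit))
  expect_match(out[2], "mean \\+ 3 SD = 0\\.2[0-9]+ um\\^2")
})

test_that("the full pipeline counts puncta accurately on synthetic fields", {
  for (seed in c(21, 22)) {
    f <- synth_puncta_image(small_field_model(), seed = seed)
    q <- quantify_puncta(f$image)
    # resolvable ground-truth objects: merge centres closer than 2 sigma
    tr <- f$truth
    d <- as.matrix(dist(cbind(tr$x_um, tr$y_um)))
    merged <- sum(d[upper.tri(d)] < 2 * small_field_model()$spot_sigma_um)
    expected <- nrow(tr) - merged
    n_lab <- max(q$labels)
    expect_lt(abs(n_lab - expected) / expected, 0.10)
  }
})

test_that("rank-order intensity analysis recovers the true intensity factor", {
  # fields of the size used in practice, two per condition, puncta pooled
  m <- puncta_field_model(field_um = c(30, 30), density = 0.3,
                          doublet_fraction = 0.15)
  measure <- function(transform, seeds) {
    sets <- lapply(seeds, function(s) {
      f <- synth_puncta_image(m, transform, seed = s)
      quantify_puncta(f$image)$puncta
    })
    do.call(rbind, sets)
  }
  pa <- measure(scaling_transform("none"), c(31, 32))

  # identical sets: slope exactly 1
  same <- puncta_scaling(pa, pa, seed = 1)
  expect_equal(same$slope, 1, tolerance = 1e-10)

  # seed-matched pairs with known factor
  for (c_true in c(1.2, 1.5)) {
    pb <- measure(scaling_transform("multiplicative", c_true), c(31, 32))
    fit <- puncta_scaling(pa, pb, seed = 2)
    expect_lt(abs(fit$slope - c_true), 0.05)
  }
})

test_that("IR standardisation yields zero-mean unit-SD vectors and correlations", {
  withr::with_seed(41, {
    num <- runif(200, 50, 150)
    den <- runif(200, 30, 60)
    cov <- rnorm(200)
  })
  z <- standardize_ir(num, den, cov, background = 10)
  expect_equal(mean(z$ratio_z), 0, tolerance = 1e-12)
  expect_equal(sd(z$ratio_z), 1, tolerance = 1e-12)
  expect_equal(mean(z$covariate_z), 0, tolerance = 1e-12)
  expect_equal(sd(z$covariate_z), 1, tolerance = 1e-12)

  # perfect anticorrelation case
  ratio <- (num - 10) / (den - 10)
  z2 <- standardize_ir(num, den, -ratio, background = 10)
  expect_equal(z2$correlation, -1)

  # independent vectors: small correlation in most replicates
  withr::with_seed(42, {
    rs <- vapply(1:40, function(i) {
      standardize_ir(runif(500, 50, 150), runif(500, 30, 60), rnorm(500),
                     background = 0)$correlation
    }, numeric(1))
  })
  expect_gte(mean(abs(rs) < 0.1), 0.95)

  # non-positive denominators excluded with a message
  den_bad <- den; den_bad[1:5] <- 5
  expect_message(z3 <- standardize_ir(num, den_bad, cov, background = 10),
                 "excluded 5")
  expect_equal(z3$n, 195)
})
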