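test_that("per-cell subsampling pools the right counts deterministically", {
  m <- amp_model_flat()
  cells <- sample_cell_amplitudes(m, 3, 150, seed = 5)
  pool <- subsample_per_cell(cells, k = 100, seed = 1)
  expect_equal(length(pool$amplitudes), 300)

  # a cell with exactly k events contributes all of them
  exact <- list(a = 1:100 + 0.5)
  p1 <- subsample_per_cell(exact, k = 100)
  expect_setequal(p1$amplitudes, exact$a)

  # determinism
  p2 <- subsample_per_cell(cells, k = 100, seed = 1)
  expect_identical(pool$amplitudes, p2$amplitudes)
  p3 <- subsample_per_cell(cells, k = 100, seed = 2)
  expect_false(identical(pool$amplitudes, p3$amplitudes))

  # strict mode names the offending cell; permissive mode warns
  short <- list(cellA = runif(150, 5, 30), cellB = runif(40, 5, 30))
  expect_error(subsample_per_cell(short, k = 100), "cellB")
  expect_warning(p4 <- subsample_per_cell(short, k = 100, strict = FALSE),
                 "fewer")
  expect_equal(length(p4$amplitudes), 140)
  expect_error(subsample_per_cell(list(), k = 100), "empty")
})

test_that("rank-order construction matches, sorts and excludes correctly", {
  x <- runif(200, 5, 50)
  pairs_id <- build_rank_order(x, x, exclude_top = 0)
  expect_equal(pairs_id$control, pairs_id$treated)
  expect_equal(pairs_id$control, sort(x))

  # elementwise doubling: every retained pair is (v, 2v)
  p2 <- build_rank_order(x, 2 * x, exclude_top = 0.01)
  expect_equal(p2$treated, 2 * p2$control)

  # 200 pairs with 1% top exclusion leave 198
  expect_equal(nrow(p2), 198)

  # count matching by seeded subsampling of the larger pool
  y <- runif(300, 5, 50)
  pm <- build_rank_order(x, y, seed = 7)
  expect_equal(attr(pm, "n_matched"), 200)
  pm2 <- build_rank_order(x, y, seed = 7)
  expect_identical(pm, pm2)

  # exclusion monotonicity: more exclusion, never more pairs
  ns <- vapply(c(0, 0.01, 0.05, 0.1, 0.5),
               function(e) nrow(build_rank_order(x, y, exclude_top = e,
                                                 seed = 1)),
               integer(1))
  expect_true(all(diff(ns) <= 0))

  expect_error(build_rank_order(numeric(0), x), "non-empty")
  expect_error(build_rank_order(c(1, 2), c(1, 2), exclude_top = 0.9),
               "fewer than 2")
})

test_that("scaling-factor fits agree with closed-form least squares", {
  x <- seq(5, 100, by = 5)
  f1 <- fit_scaling_factor(data.frame(control = x, treated = x))
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0)
  expect_equal(f1$r_squared, 1)

  f2 <- fit_scaling_factor(data.frame(control = x, treated = x + 5))
  expect_equal(f2$slope, 1)
  expect_equal(f2$intercept, 5)

  f3 <- fit_scaling_factor(data.frame(control = x, treated = 1.43 * x))
  expect_equal(f3$slope, 1.43)
  expect_equal(f3$intercept, 0, tolerance = 1e-12)

  # matches textbook OLS on arbitrary pairs
  withr::with_seed(3, {
    xx <- sort(rlnorm(50, log(12), 0.3))
    yy <- sort(rlnorm(50, log(15), 0.3))
  })
  ff <- fit_scaling_factor(data.frame(control = xx, treated = yy))
  b_hat <- sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
  expect_equal(ff$slope, b_hat)
  expect_equal(ff$intercept, mean(yy) - b_hat * mean(xx))

  # fit_fraction restricts to the lowest ranks
  fl <- fit_scaling_factor(data.frame(control = xx, treated = yy),
                           fit_fraction = 0.5)
  expect_equal(fl$n_pairs, 25)

  # through-origin diagnostic fit
  fo <- fit_scaling_factor(data.frame(control = x, treated = 2 * x),
                           intercept = FALSE)
  expect_equal(fo$slope, 2)
  expect_equal(fo$intercept, 0)

  expect_error(fit_scaling_factor(data.frame(control = rep(3, 10),
                                             treated = 1:10)),
               "zero variance")
})

test_that("the pipeline recovers multiplicative factors and the null", {
  m <- amp_model_flat()
  # null: same distribution in both conditions
  slopes <- vapply(1:20, function(s) {
    ctrl <- sample_cell_amplitudes(m, 12, 150, seed = 100 + s)
    trt <- sample_cell_amplitudes(m, 12, 150, seed = 300 + s)
    scaling_pipeline(ctrl, trt, seed = 500 + s)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.02)

  # recovery across the factor grid
  for (c_true in c(1.2, 1.43, 2.0)) {
    rec <- vapply(1:10, function(s) {
      ctrl <- sample_cell_amplitudes(m, 20, 150, seed = 1000 + s)
      trt <- scaled_cells(m, 20, 150, c_true, seed = 2000 + s)
      scaling_pipeline(ctrl, trt, seed = 3000 + s)$slope
    }, numeric(1))
    expect_lt(abs(mean(rec) - c_true), 0.03)
  }

  # additive shift: slope near 1, intercept near the shift
  shift <- 5
  add <- vapply(1:10, function(s) {
    ctrl <- sample_cell_amplitudes(m, 20, 150, seed = 1000 + s)
    trt <- sample_cell_amplitudes(m, 20, 150, seed = 2000 + s)
    trt[] <- lapply(trt, `+`, shift)
    fit <- scaling_pipeline(ctrl, trt, seed = 3000 + s)
    c(fit$slope, fit$intercept)
  }, numeric(2))
  expect_lt(abs(mean(add[1, ]) - 1), 0.03)
  expect_lt(abs(mean(add[2, ]) - shift), 0.5)
})

test_that("the fitted slope is scale-equivariant", {
  x <- sort(rlnorm(500, log(12), 0.35))
  y <- sort(rlnorm(500, log(12), 0.35))
  base <- fit_scaling_factor(data.frame(control = x, treated = y))$slope
  for (g in c(0.5, 1.7, 3)) {
    fg <- fit_scaling_factor(data.frame(control = x, treated = g * y))$slope
    expect_equal(fg, g * base)
  }
})

test_that("rank-sum comparison matches exact enumeration and extremes", {
  same <- compare_rank_distributions(c(2, 4, 6, 8), c(2, 4, 6, 8))
  expect_gt(same$p_value, 0.95)

  r <- compare_rank_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)

  # exact enumeration oracle on random small samples (with and without ties)
  withr::with_seed(8, {
    for (i in 1:6) {
      a <- sample(1:10, 5, replace = i > 3)
      b <- sample(2:12, 6, replace = i > 3)
      got <- compare_rank_distributions(a, b)
      expect_equal(got$p_value, mw_enumeration_oracle(a, b),
                   tolerance = 1e-12)
    }
  })

  # agrees with the standard implementation in the no-ties regime
  withr::with_seed(9, {
    a <- rnorm(12); b <- rnorm(15) + 0.5
  })
  got <- compare_rank_distributions(a, b)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(got$p_value, unname(ref$p.value))

  # large separated samples: overwhelming evidence
  withr::with_seed(10, {
    big <- compare_rank_distributions(rnorm(300), rnorm(300) + 2)
  })
  expect_lt(big$p_value, 1e-4)

  deg <- compare_rank_distributions(rep(3, 5), rep(3, 7))
  expect_true(deg$degenerate)
})
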