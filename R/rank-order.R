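#' Subsample a fixed number of amplitudes from each cell
#'
#' High-frequency cells would otherwise dominate a pooled amplitude
#' comparison, so a fixed number of events (conventionally 100) is drawn
#' uniformly without replacement from every recording before pooling.
#'
#' @param cells a `cell_amplitudes` list (or plain list of numeric
#'   vectors), one element per cell.
#' @param k events drawn per cell. Default 100.
#' @param seed optional integer seed.
#' @param strict if `TRUE` (default), a cell with fewer than `k` events is
#'   an error naming the cell; if `FALSE`, all of its events are taken and
#'   a warning is raised.
#' @param condition label for the pool; defaults to the condition attribute
#'   of `cells` when present.
#' @return object of class `pooled_sample`: list with `amplitudes` (the
#'   pooled draw), `condition`, `k`, `cell_ids`, `seed`.
#' @export
subsample_per_cell <- function(cells, k = 100, seed = NULL, strict = TRUE,
                               condition = NULL) {
  if (length(cells) == 0) stopf("empty cell list")
  if (!is_count(k)) stopf("k must be a positive integer")
  condition <- condition %||% attr(cells, "condition") %||% "unlabelled"
  ids <- names(cells) %||% sprintf("cell%02d", seq_along(cells))
  short <- which(lengths(cells) < k)
  if (length(short) > 0) {
    if (strict)
      stopf("cell '%s' has only %d events (< k = %d); use strict = FALSE to take all",
            ids[short[1]], length(cells[[short[1]]]), k)
    warnf("%d cell(s) have fewer than k = %d events; taking all of their events",
          length(short), k)
  }
  pooled <- with_seed_if(seed, {
    unlist(lapply(cells, function(a) {
      if (length(a) <= k) a else sample(a, k)
    }), use.names = FALSE)
  })
  structure(list(amplitudes = pooled, condition = condition, k = k,
                 cell_ids = ids, seed = seed),
            class = "pooled_sample")
}

#' @export
print.pooled_sample <- function(x, ...) {
  cat(sprintf("Pooled sample '%s': %d amplitudes from %d cells (k = %d)\n",
              x$condition, length(x$amplitudes), length(x$cell_ids), x$k))
  invisible(x)
}

#' Build rank-order pairs from two pooled samples
#'
#' If the pools differ in size the larger is randomly subsampled (seeded)
#' down to the smaller, mirroring the count-matching used for punctum
#' intensities. Both pools are then sorted ascending (stable sort) and
#' paired by rank; the top `ceiling(exclude_top * n)` rank pairs are
#' dropped, since the largest amplitudes are outlier-prone and distort the
#' scaling-factor fit.
#'
#' @param control,treated [subsample_per_cell()] pools, or plain numeric
#'   vectors.
#' @param exclude_top fraction of top rank pairs to exclude. Default 0.01.
#' @param seed optional integer seed for the count-matching subsample.
#' @return data frame of class `rank_pairs` with ascending columns
#'   `control` and `treated`.
#' @export
build_rank_order <- function(control, treated, exclude_top = 0.01,
                             seed = NULL) {
  a <- pool_values(control)
  b <- pool_values(treated)
  if (length(a) == 0 || length(b) == 0) stopf("both pools must be non-empty")
  if (!is_number(exclude_top) || exclude_top < 0 || exclude_top >= 1)
    stopf("exclude_top must be in [0, 1)")
  n <- min(length(a), length(b))
  matched <- with_seed_if(seed, {
    list(a = if (length(a) > n) sample(a, n) else a,
         b = if (length(b) > n) sample(b, n) else b)
  })
  x <- sort(matched$a, method = "radix")
  y <- sort(matched$b, method = "radix")
  n_drop <- ceiling(exclude_top * n)
  if (n - n_drop < 2) stopf("top exclusion leaves fewer than 2 rank pairs")
  keep <- seq_len(n - n_drop)
  out <- data.frame(control = x[keep], treated = y[keep])
  class(out) <- c("rank_pairs", "data.frame")
  attr(out, "exclude_top") <- exclude_top
  attr(out, "n_matched") <- n
  out
}

pool_values <- function(x) {
  if (inherits(x, "pooled_sample")) return(x$amplitudes)
  if (is.numeric(x)) return(as.numeric(x))
  stopf("expected a pooled_sample or a numeric vector")
}

#' Fit the scaling factor to rank-order pairs
#'
#' Ordinary least squares of treated against control values over the lowest
#' `fit_fraction` of rank pairs. The fitted slope is the scaling factor;
#' under multiplicative scaling by `c` the expected slope is `c` with
#' intercept near zero, while a purely additive change of `a` gives slope
#' near 1 and intercept near `a`. A through-origin fit is available as a
#' diagnostic (`intercept = FALSE`).
#'
#' `fit_fraction = 1` is the convention for mEPSC amplitude pools (after
#' their top-1% exclusion); punctum intensity analyses conventionally fit
#' the lowest 90% of ranks because the brightest puncta deviate from
#' linearity.
#'
#' @param pairs a [build_rank_order()] result, or a data frame with columns
#'   `control` and `treated` sorted ascending.
#' @param fit_fraction fraction of the lowest ranks entering the fit,
#'   in (0, 1]. Default 1.
#' @param intercept fit a free intercept (default `TRUE`).
#' @return object of class `rank_order_fit`: `slope`, `intercept`,
#'   `r_squared`, `n_pairs` (fitted pairs), `fit_fraction`, `pairs`.
#' @export
fit_scaling_factor <- function(pairs, fit_fraction = 1.0, intercept = TRUE) {
  stopifnot(is.data.frame(pairs),
            all(c("control", "treated") %in% names(pairs)))
  if (!is_number(fit_fraction) || fit_fraction <= 0 || fit_fraction > 1)
    stopf("fit_fraction must be in (0, 1]")
  n <- nrow(pairs)
  m <- max(2L, floor(fit_fraction * n))
  if (n < 2) stopf("need at least 2 rank pairs")
  x <- pairs$control[seq_len(m)]
  y <- pairs$treated[seq_len(m)]
  if (var(x) == 0) stopf("zero variance in control values; slope undefined")
  fit <- if (intercept) lm(y ~ x) else lm(y ~ x + 0)
  co <- coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  structure(list(slope = unname(co[["x"]]),
                 intercept = if (intercept) unname(co[[1]]) else 0,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n_pairs = m,
                 fit_fraction = fit_fraction,
                 free_intercept = intercept,
                 pairs = pairs),
            class = "rank_order_fit")
}

#' @export
print.rank_order_fit <- function(x, ...) {
  cat(sprintf("Rank-order fit: slope = %.3f (scaling factor), intercept = %.3f\n",
              x$slope, x$intercept))
  cat(sprintf("  %d pairs fitted (lowest %.0f%% of ranks), r2 = %.4f\n",
              x$n_pairs, 100 * x$fit_fraction, x$r_squared))
  invisible(x)
}

#' End-to-end rank-order scaling statistic for mEPSC amplitudes
#'
#' Runs the full procedure: subsample `k` amplitudes per cell in each
#' condition, pool, count-match, sort ascending, exclude the top
#' `exclude_top` fraction of rank pairs, and fit the scaling factor over
#' the lowest `fit_fraction` of the remaining ranks. Deterministic for a
#' given seed.
#'
#' @param control_cells,treated_cells per-cell amplitude lists
#'   (`cell_amplitudes` or plain lists of numeric vectors).
#' @param k amplitudes subsampled per cell. Default 100.
#' @param exclude_top top rank-pair exclusion fraction. Default 0.01.
#' @param fit_fraction fraction of lowest ranks fitted. Default 1.
#' @param seed optional integer seed controlling subsampling and matching.
#' @param intercept free-intercept fit (default) or through-origin.
#' @param strict passed to [subsample_per_cell()].
#' @return a [fit_scaling_factor()] result.
#' @examples
#' ctrl <- sample_cell_amplitudes(amplitude_model(cell_cv = 0), 6, 150, seed = 1)
#' trt <- lapply(
#'   sample_cell_amplitudes(amplitude_model(cell_cv = 0), 6, 150, seed = 2),
#'   function(a) 1.4 * a)
#' scaling_pipeline(ctrl, trt, seed = 3)
#' @export
scaling_pipeline <- function(control_cells, treated_cells, k = 100,
                             exclude_top = 0.01, fit_fraction = 1.0,
                             seed = NULL, intercept = TRUE, strict = TRUE) {
  ctrl <- subsample_per_cell(control_cells, k, seed = child_seed(seed, 1),
                             strict = strict, condition = "control")
  trt <- subsample_per_cell(treated_cells, k, seed = child_seed(seed, 2),
                            strict = strict, condition = "treated")
  pairs <- build_rank_order(ctrl, trt, exclude_top = exclude_top,
                            seed = child_seed(seed, 3))
  fit_scaling_factor(pairs, fit_fraction = fit_fraction,
                     intercept = intercept)
}

#' Rank-sum comparison of two value distributions
#'
#' Mann-Whitney U with a two-sided p value: exact when feasible (the exact
#' null distribution of U without ties, or full enumeration of group
#' assignments when ties are present and the combination count is small),
#' otherwise a normal approximation with tie correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact_limit maximum `n * m` for the exact no-ties distribution,
#'   and maximum number of enumerated assignments in the tied case.
#' @return list: `U` (statistic for `a`), `p_value` (two-sided), `method`,
#'   `degenerate` (`TRUE` when all pooled values tie).
#' @export
compare_rank_distributions <- function(a, b, exact_limit = 1e4) {
  if (length(a) == 0 || length(b) == 0) stopf("both samples must be non-empty")
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(pooled))
  if (all(pooled == pooled[1]))
    return(list(U = U, p_value = 1, method = "degenerate", degenerate = TRUE))
  if (!ties && n * m <= exact_limit) {
    p_lo <- stats::pwilcox(U, n, m)
    p_hi <- 1 - stats::pwilcox(U - 1, n, m)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U, p_value = p, method = "exact", degenerate = FALSE))
  }
  if (ties && choose(n + m, n) <= exact_limit) {
    idx <- utils::combn(n + m, n)
    r_all <- rank(pooled)
    Us <- apply(idx, 2, function(j) sum(r_all[j]) - n * (n + 1) / 2)
    p_lo <- mean(Us <= U)
    p_hi <- mean(Us >= U)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U, p_value = p, method = "enumeration",
                degenerate = FALSE))
  }
  mu <- n * m / 2
  tie_tab <- table(pooled)
  N <- n + m
  sig2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- (U - mu) / sqrt(sig2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal", degenerate = FALSE)
}
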