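# Shared fixtures and independent oracles.

# Homogeneous amplitude population used by most scaling tests: the
# recovery statements concern the statistic itself, so the per-cell
# heterogeneity knob is off unless a test turns it on.
amp_model_flat <- function(...) amplitude_model(cell_cv = 0, ...)

# Treated condition: independent per-cell draws from `model`, every
# amplitude multiplied by `factor`.
scaled_cells <- function(model, n_cells, events_per_cell, factor, seed) {
  cells <- sample_cell_amplitudes(model, n_cells, events_per_cell,
                                  seed = seed, condition = "treated")
  cells[] <- lapply(cells, `*`, factor)
  cells
}

# Brute-force Li minimum-cross-entropy oracle: direct evaluation of the
# criterion at every histogram cut point, no cumulative-sum shortcuts.
li_threshold_bruteforce <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  bin_w <- (hi - lo) / n_bins
  shift <- if (lo <= 0) -lo + bin_w else 0
  v <- v + shift
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  h <- hist(v, breaks = breaks, plot = FALSE)
  best <- Inf; best_cut <- NA
  for (i in seq_len(n_bins - 1)) {
    b <- h$mids[seq_len(i)]; wb <- h$counts[seq_len(i)]
    f <- h$mids[(i + 1):n_bins]; wf <- h$counts[(i + 1):n_bins]
    if (sum(wb) == 0 || sum(wf) == 0) next
    mu_b <- sum(wb * b) / sum(wb)
    mu_f <- sum(wf * f) / sum(wf)
    # cross entropy up to a threshold-free additive constant
    obj <- -(sum(wb * b) * log(mu_b) + sum(wf * f) * log(mu_f))
    if (obj < best) { best <- obj; best_cut <- h$breaks[i + 1] }
  }
  best_cut - shift
}

# Exact Mann-Whitney two-sided p by enumeration of all group assignments.
mw_enumeration_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  Us <- apply(idx, 2, function(j) sum(r[j]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# Synthetic mEPSC recording whose events respect a minimum separation, so
# ground-truth matching is unambiguous.
separated_mepsc_trace <- function(n_events, amp_model, tmodel, duration_s,
                                  min_sep_s, seed) {
  withr::with_seed(seed, {
    t_s <- sort(runif(4 * n_events, 0.1, duration_s - 0.1))
    keep <- c(TRUE, diff(t_s) >= min_sep_s)
    t_s <- head(t_s[keep], n_events)
    amp <- synscale:::draw_truncated(amp_model, 1, length(t_s), 1000L)
    truth <- data.frame(t_s = t_s, amp_pA = amp)
    list(trace = synth_trace(truth, tmodel, duration_s,
                             seed = seed + 5000L),
         truth = truth)
  })
}

# Match detected events to ground truth within a time window; returns
# recall, precision and amplitude errors of the matched pairs.
match_events <- function(detected, truth, window_s = 0.005) {
  if (nrow(truth) == 0 || nrow(detected) == 0)
    return(list(recall = 0, precision = 0, amp_err = numeric(0)))
  d <- abs(outer(detected$peak_t, truth$t_s, `-`))
  hit <- apply(d, 2, min) < window_s
  j <- apply(d, 2, which.min)
  amp_err <- detected$amplitude[j[hit]] - truth$amp_pA[hit]
  used <- unique(j[hit])
  list(recall = mean(hit),
       precision = length(used) / nrow(detected),
       amp_err = amp_err)
}

# Small punctum field for imaging tests (fast to render and segment).
small_field_model <- function(...) {
  puncta_field_model(field_um = c(20, 20), density = 0.3,
                     doublet_fraction = 0.15, ...)
}

# Render a bare matrix holding Gaussian spots at given centres (px) and
# integrated intensities, on a constant background -- a controlled input
# for segmentation tests, independent of the package generator.
spot_matrix <- function(n, centres, intensities, sigma_px, background = 0) {
  img <- matrix(background, n, n)
  for (i in seq_len(nrow(centres))) {
    x0 <- centres[i, 1]; y0 <- centres[i, 2]
    gx <- pnorm(1:n + .5, x0, sigma_px) - pnorm(1:n - .5, x0, sigma_px)
    gy <- pnorm(1:n + .5, y0, sigma_px) - pnorm(1:n - .5, y0, sigma_px)
    img <- img + intensities[i] * outer(gx, gy)
  }
  img
}
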