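#' Detect miniature synaptic events in a voltage-clamp trace
#'
#' Events are deflections in the configured polarity whose peak amplitude,
#' measured relative to a running local baseline, reaches `threshold_pa`.
#' The local baseline is a running median over the `baseline_window_ms`
#' preceding each sample. Candidate peaks are located on a lightly smoothed
#' copy of the deflection (a `smooth_ms` moving average, which suppresses
#' single-sample noise excursions); amplitudes are then read from the
#' unsmoothed deflection at the local extremum. Peaks closer than
#' `min_separation_ms` to a previous peak are merged, keeping the largest.
#'
#' AMPAR-mEPSCs are conventionally detected with a 5 pA threshold and
#' NMDAR-mEPSCs with a 10 pA threshold; both are settable here.
#'
#' @param tr a [trace()] of kind `voltage_clamp_current`.
#' @param threshold_pa detection threshold in pA (> 0). Default 5.
#' @param min_separation_ms merge window between peaks, ms. Default 5.
#' @param baseline_window_ms running-median baseline window, ms. Default 50.
#' @param smooth_ms detection smoothing window, ms. Default 1.
#' @param polarity -1 for inward (negative-going) events, +1 for outward.
#' @param cell_id label copied into the event table.
#' @return data frame of class `event_table`: `cell_id`, `onset_t`,
#'   `peak_t` (s), `amplitude` (pA, positive magnitude), sorted by onset.
#' @seealso [summarize_cell()], [simulate_mepsc_trace()]
#' @export
detect_events <- function(tr, threshold_pa = 5, min_separation_ms = 5,
                          baseline_window_ms = 50, smooth_ms = 1,
                          polarity = -1, cell_id = "cell01") {
  stopifnot(inherits(tr, "synscale_trace"))
  if (tr$signal_kind != "voltage_clamp_current")
    stopf("detect_events expects a voltage-clamp current trace")
  if (!is_number(threshold_pa) || threshold_pa <= 0)
    stopf("threshold_pa must be > 0")
  fs <- tr$sampling_rate
  x <- tr$samples
  wb <- max(3L, round(baseline_window_ms / 1000 * fs))
  if (length(x) <= wb)
    stopf("trace shorter than the baseline window")

  base <- trailing_median(x, wb)
  d <- polarity * (x - base)           # deflection, positive in event polarity

  ws <- max(1L, round(smooth_ms / 1000 * fs))
  ds <- if (ws > 1) moving_average(d, ws) else d

  above <- ds >= threshold_pa * attenuation_guard(ws)
  peaks <- local_maxima_in_runs(ds, above)
  if (length(peaks) == 0) return(empty_event_table())

  # refine each peak on the raw deflection within half the smoothing
  # window (wider windows inflate amplitudes by the local noise maximum)
  half <- max(1L, ws %/% 2L)
  peak_idx <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(length(d), p + half)
    as.integer(lo + which.max(d[lo:hi]) - 1L)
  }, integer(1))
  amp <- d[peak_idx]

  keep <- amp >= threshold_pa
  peak_idx <- peak_idx[keep]; amp <- amp[keep]
  if (length(peak_idx) == 0) return(empty_event_table())

  merged <- merge_close_peaks(peak_idx, amp, round(min_separation_ms / 1000 * fs))
  peak_idx <- merged$idx; amp <- merged$amp

  # decay-tail re-arm: a later peak is a new event only if the deflection
  # dipped below half the threshold in between; otherwise it is ripple on
  # the previous event's decay and the larger peak is kept
  rearm <- merge_unarmed_peaks(ds, peak_idx, amp, 0.5 * threshold_pa)
  peak_idx <- rearm$idx; amp <- rearm$amp

  onset_idx <- vapply(seq_along(peak_idx), function(i) {
    p <- peak_idx[i]
    lo <- max(1L, p - wb)
    seg <- d[lo:p]
    below <- which(seg <= 0.1 * amp[i])
    as.integer(if (length(below) == 0) lo else lo + max(below) - 1L)
  }, integer(1))

  out <- data.frame(cell_id = cell_id,
                    onset_t = (onset_idx - 1) / fs,
                    peak_t = (peak_idx - 1) / fs,
                    amplitude = amp)
  out <- out[order(out$onset_t), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

empty_event_table <- function() {
  out <- data.frame(cell_id = character(0), onset_t = numeric(0),
                    peak_t = numeric(0), amplitude = numeric(0))
  class(out) <- c("event_table", "data.frame")
  out
}

# Running median over the window *preceding* each sample: a centred running
# median lagged by half a window, padded at the start.
trailing_median <- function(x, w) {
  k <- w + (w + 1) %% 2           # next odd width
  m <- runmed(x, k, endrule = "median")
  lag <- (k - 1L) %/% 2L
  c(rep(m[1], lag), m)[seq_along(x)]
}

moving_average <- function(x, w) {
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  y[is.na(y)] <- 0
  y
}

# A w-sample boxcar attenuates a sharp event peak (about 15% for the
# default 0.5/5 ms kernel at 1 ms smoothing); pre-screen candidates at the
# correspondingly relaxed level and let the raw-amplitude test make the
# final call.
attenuation_guard <- function(w) if (w > 1) 0.85 else 1

# Index of the maximum within each contiguous TRUE run.
local_maxima_in_runs <- function(x, above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  vapply(idx, function(i) {
    s <- starts[i]; e <- ends[i]
    s + which.max(x[s:e]) - 1L
  }, integer(1))
}

merge_close_peaks <- function(idx, amp, min_sep) {
  o <- order(idx)
  idx <- idx[o]; amp <- amp[o]
  keep_idx <- integer(0); keep_amp <- numeric(0)
  for (i in seq_along(idx)) {
    if (length(keep_idx) > 0 && idx[i] - keep_idx[length(keep_idx)] < min_sep) {
      if (amp[i] > keep_amp[length(keep_amp)]) {
        keep_idx[length(keep_idx)] <- idx[i]
        keep_amp[length(keep_amp)] <- amp[i]
      }
    } else {
      keep_idx <- c(keep_idx, idx[i])
      keep_amp <- c(keep_amp, amp[i])
    }
  }
  list(idx = keep_idx, amp = keep_amp)
}

merge_unarmed_peaks <- function(ds, idx, amp, rearm_level) {
  if (length(idx) < 2) return(list(idx = idx, amp = amp))
  keep_idx <- idx[1]; keep_amp <- amp[1]
  for (i in 2:length(idx)) {
    last <- length(keep_idx)
    gap_min <- min(ds[keep_idx[last]:idx[i]])
    if (gap_min > rearm_level) {
      if (amp[i] > keep_amp[last]) {
        keep_idx[last] <- idx[i]
        keep_amp[last] <- amp[i]
      }
    } else {
      keep_idx <- c(keep_idx, idx[i])
      keep_amp <- c(keep_amp, amp[i])
    }
  }
  list(idx = keep_idx, amp = keep_amp)
}

#' Summarise a cell's detected events
#'
#' @param events an event table from [detect_events()] (or any data frame
#'   with `cell_id` and `amplitude` columns).
#' @param duration_s analysed recording duration in seconds (> 0);
#'   recordings are conventionally analysed over a 4-5 min window.
#' @return one-row data frame: `cell_id`, `mean_amplitude` (pA, `NA` when no
#'   events), `frequency` (Hz, exactly `n_events / duration_s`), `n_events`,
#'   `duration_s`.
#' @export
summarize_cell <- function(events, duration_s) {
  if (!is_number(duration_s) || duration_s <= 0)
    stopf("duration_s must be > 0")
  n <- nrow(events)
  data.frame(
    cell_id = if (n > 0) events$cell_id[1] else NA_character_,
    mean_amplitude = if (n > 0) mean(events$amplitude) else NA_real_,
    frequency = n / duration_s,
    n_events = n,
    duration_s = duration_s)
}
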