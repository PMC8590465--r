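#' Initial slope of a field EPSP
#'
#' Measures population synaptic strength as the slope of the field
#' potential's rising phase, fitted by ordinary least squares to the
#' contiguous run of samples whose amplitude lies between 10% and 40% of
#' the baseline-to-peak excursion (the band is configurable). The response
#' polarity (fEPSPs are normally negative-going) is inferred from the
#' largest post-stimulus deflection; a blanking window after the stimulus
#' excludes the stimulus artifact.
#'
#' @param tr a [trace()] of kind `field_potential`.
#' @param stim_t stimulus time, s.
#' @param blank_ms artifact blanking window after `stim_t`, ms. Default 2.
#' @param baseline_ms pre-stimulus window used for the baseline, ms.
#' @param band amplitude band of the rising phase as fractions of peak,
#'   default `c(0.1, 0.4)`.
#' @param response_window_ms how far after the stimulus to search for the
#'   response peak, ms.
#' @param noise_mult the response peak must exceed `noise_mult` times the
#'   baseline SD, else no detectable response is declared.
#' @return list of class `fepsp_slope`: `slope` (signal units per ms,
#'   signed), `peak` (baseline-subtracted peak value), `t_band` (start/end
#'   of the fitted run, s), `n` (samples fitted), `r_squared`.
#' @seealso [fepsp_normalize()]
#' @export
fepsp_initial_slope <- function(tr, stim_t, blank_ms = 2, baseline_ms = 10,
                                band = c(0.1, 0.4), response_window_ms = 50,
                                noise_mult = 3) {
  stopifnot(inherits(tr, "synscale_trace"))
  if (tr$signal_kind != "field_potential")
    stopf("fepsp_initial_slope expects a field-potential trace")
  fs <- tr$sampling_rate
  x <- tr$samples
  i_stim <- floor(stim_t * fs) + 1L
  if (i_stim < 2 || i_stim >= length(x)) stopf("stim_t outside the trace")

  i_b0 <- max(1L, i_stim - round(baseline_ms / 1000 * fs))
  baseline <- mean(x[i_b0:(i_stim - 1L)])
  noise_sd <- sd(x[i_b0:(i_stim - 1L)])

  i_start <- i_stim + round(blank_ms / 1000 * fs)
  i_end <- min(length(x), i_stim + round(response_window_ms / 1000 * fs))
  if (i_start >= i_end) stopf("no samples after the blanking window")
  seg <- x[i_start:i_end] - baseline

  i_peak <- which.max(abs(seg))
  peak <- seg[i_peak]
  if (is.finite(noise_sd) && noise_sd > 0 && abs(peak) < noise_mult * noise_sd)
    stopf("no detectable response above the noise floor")

  # contiguous run within the amplitude band on the rising limb before peak
  frac <- seg[1:i_peak] / peak       # 0..1 along the rising phase
  inside <- frac >= band[1] & frac <= band[2]
  if (!any(inside)) stopf("no samples inside the %g-%g%% amplitude band",
                          100 * band[1], 100 * band[2])
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ri <- which(runs$values)
  last <- ri[length(ri)]             # run adjacent to the peak
  sel <- starts[last]:ends[last]
  if (length(sel) < 2) stopf("amplitude band too narrow at this sampling rate")

  t_ms <- (i_start + sel - 2L) / fs * 1000
  fit <- lm(seg[sel] ~ t_ms)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((seg[sel] - mean(seg[sel]))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 peak = peak,
                 t_band = range(t_ms) / 1000,
                 n = length(sel),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
            class = "fepsp_slope")
}

#' @export
print.fepsp_slope <- function(x, ...) {
  cat(sprintf("fEPSP initial slope: %.4g /ms (peak %.4g, %d samples, r2 = %.3f)\n",
              x$slope, x$peak, x$n, x$r_squared))
  invisible(x)
}

#' Normalise a series of fEPSP slopes to a pre-conditioning baseline
#'
#' Expresses slopes as percentages of the average over the first
#' `n_baseline` responses, the usual presentation of drug-induced synaptic
#' potentiation time courses.
#'
#' @param slopes numeric vector of slopes in acquisition order.
#' @param n_baseline number of leading responses forming the baseline.
#' @return slopes as percent of baseline average.
#' @export
fepsp_normalize <- function(slopes, n_baseline) {
  if (!is_count(n_baseline) || n_baseline > length(slopes))
    stopf("n_baseline must be a count <= length(slopes)")
  b <- mean(slopes[seq_len(n_baseline)])
  if (b == 0) stopf("zero baseline average")
  100 * slopes / b
}

#' AMPA and NMDA components of evoked EPSCs
#'
#' The AMPAR component is the baseline-subtracted peak of the response
#' recorded at -70 mV; the NMDAR component is the baseline-subtracted value
#' of the +40 mV response exactly 150 ms after EPSC onset (linearly
#' interpolated between samples). Both are reported as positive magnitudes;
#' the AMPA/NMDA ratio is their quotient.
#'
#' @param trace_ampa,trace_nmda voltage-clamp [trace()]s at -70 and +40 mV.
#' @param onset_t EPSC onset time, s. Both traces must extend at least
#'   150 ms beyond it.
#' @param baseline_ms pre-onset baseline window, ms.
#' @param nmda_at_ms delay of the NMDAR measurement after onset, ms.
#' @param response_window_ms window after onset searched for the AMPA peak.
#' @return list of class `evoked_measures`: `ampa_peak`, `nmda_at_150ms`
#'   (pA), `ratio` (NA with `ratio_defined = FALSE` when the NMDAR
#'   measurement is not positive).
#' @export
evoked_measures <- function(trace_ampa, trace_nmda, onset_t,
                            baseline_ms = 10, nmda_at_ms = 150,
                            response_window_ms = 50) {
  stopifnot(inherits(trace_ampa, "synscale_trace"),
            inherits(trace_nmda, "synscale_trace"))
  need <- onset_t + nmda_at_ms / 1000
  for (tr in list(trace_ampa, trace_nmda))
    if (length(tr$samples) / tr$sampling_rate < need)
      stopf("trace does not contain onset_t + %g ms", nmda_at_ms)

  ampa <- deflection(trace_ampa, onset_t, baseline_ms)
  i_end <- min(length(ampa$d),
               ampa$i_on + round(response_window_ms / 1000 *
                                   trace_ampa$sampling_rate))
  ampa_peak <- max(abs(ampa$d[ampa$i_on:i_end]))

  nmda <- deflection(trace_nmda, onset_t, baseline_ms)
  t_target <- onset_t + nmda_at_ms / 1000
  nmda_150 <- interp_at(nmda$d, trace_nmda$sampling_rate, t_target)

  defined <- is.finite(nmda_150) && nmda_150 > 0
  structure(list(ampa_peak = ampa_peak,
                 nmda_at_150ms = nmda_150,
                 ratio = if (defined) ampa_peak / nmda_150 else NA_real_,
                 ratio_defined = defined),
            class = "evoked_measures")
}

deflection <- function(tr, onset_t, baseline_ms) {
  fs <- tr$sampling_rate
  i_on <- floor(onset_t * fs) + 1L
  if (i_on < 2) stopf("onset_t too early for a pre-onset baseline")
  i_b0 <- max(1L, i_on - round(baseline_ms / 1000 * fs))
  base <- median(tr$samples[i_b0:(i_on - 1L)])
  list(d = tr$samples - base, i_on = i_on)
}

interp_at <- function(x, fs, t) {
  pos <- t * fs + 1
  i0 <- floor(pos)
  if (i0 >= length(x)) return(x[length(x)])
  frac <- pos - i0
  x[i0] * (1 - frac) + x[i0 + 1L] * frac
}

#' @export
print.evoked_measures <- function(x, ...) {
  cat(sprintf("Evoked EPSC: AMPA peak %.4g pA, NMDA at +150 ms %.4g pA\n",
              x$ampa_peak, x$nmda_at_150ms))
  if (x$ratio_defined)
    cat(sprintf("  AMPA/NMDA ratio: %.4g\n", x$ratio))
  else cat("  AMPA/NMDA ratio: undefined (non-positive NMDA measurement)\n")
  invisible(x)
}
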