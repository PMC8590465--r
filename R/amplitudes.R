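#' Theoretical lateral resolution of a confocal microscope
#'
#' Computes the diffraction-limited lateral resolution `0.51 * lambda / NA`
#' in nanometres. For a 488 nm excitation line and a 1.4 NA objective this
#' evaluates to 177.8 nm; [lateral_resolution_nm()] rounds to the nearest
#' integer nanometre (178 nm).
#'
#' @param lambda_exc excitation wavelength in nm (>= 0).
#' @param numerical_aperture objective numerical aperture (> 0).
#' @return resolution in nm.
#' @examples
#' lateral_resolution(488, 1.4)
#' lateral_resolution_nm(488, 1.4)
#' @export
lateral_resolution <- function(lambda_exc, numerical_aperture) {
  if (!is_number(lambda_exc) || lambda_exc < 0)
    stopf("lambda_exc must be a non-negative number")
  if (!is_number(numerical_aperture) || numerical_aperture <= 0)
    stopf("numerical_aperture must be a positive number")
  0.51 * lambda_exc / numerical_aperture
}

#' @rdname lateral_resolution
#' @export
lateral_resolution_nm <- function(lambda_exc, numerical_aperture) {
  round(lateral_resolution(lambda_exc, numerical_aperture))
}

#' mEPSC amplitude population model
#'
#' Describes the per-cell distribution of mEPSC peak amplitudes as a
#' log-normal population truncated at a detection floor, with optional
#' cell-to-cell heterogeneity expressed as a log-normal multiplicative
#' factor of unit mean and coefficient of variation `cell_cv`.
#'
#' The log-normal family is a modelling choice: mEPSC amplitude histograms
#' are right-skewed with strictly positive support. The detection floor
#' mirrors the acquisition-side detection threshold (events smaller than the
#' floor are never observed), and truncation is enforced by redraw so that
#' a scaled population remains an exact scalar multiple of the control
#' population in distribution.
#'
#' @param mu_log location of log-amplitude (log pA). Default `log(12)`,
#'   i.e. a median amplitude of 12 pA.
#' @param sigma_log dispersion of log-amplitude (> 0). Default 0.35
#'   (amplitude CV of roughly 36%).
#' @param detection_floor minimum observable amplitude in pA (>= 0).
#'   Default 5 pA, the usual AMPAR-mEPSC detection threshold.
#' @param cell_cv coefficient of variation of the per-cell multiplicative
#'   factor (>= 0). Default 0.1.
#' @return an object of class `amplitude_model`.
#' @seealso [sample_cell_amplitudes()], [apply_scaling()]
#' @export
amplitude_model <- function(mu_log = log(12), sigma_log = 0.35,
                            detection_floor = 5, cell_cv = 0.1) {
  if (!is_number(sigma_log) || sigma_log < 0)
    stopf("sigma_log must be >= 0")
  if (!is_number(detection_floor) || detection_floor < 0)
    stopf("detection_floor must be >= 0")
  if (!is_number(cell_cv) || cell_cv < 0)
    stopf("cell_cv must be >= 0")
  structure(
    list(family = "log-normal", mu_log = mu_log, sigma_log = sigma_log,
         detection_floor = detection_floor, cell_cv = cell_cv),
    class = "amplitude_model")
}

#' @export
print.amplitude_model <- function(x, ...) {
  cat(sprintf(
    "Amplitude model: log-normal(mu_log = %.3f, sigma_log = %.3f)\n",
    x$mu_log, x$sigma_log))
  cat(sprintf("  detection floor: %.3g pA; cell CV: %.3g\n",
              x$detection_floor, x$cell_cv))
  invisible(x)
}

#' Scaling transform applied to an amplitude or intensity population
#'
#' Multiplicative scaling multiplies every value by a common factor `c`;
#' additive change adds a fixed offset `a`. The rank-order statistic is
#' designed to distinguish the two: multiplicative change gives a fitted
#' slope of `c` with intercept near zero, additive change a slope near 1
#' with intercept near `a`.
#'
#' @param mode one of `"none"`, `"multiplicative"`, `"additive"`.
#' @param factor multiplicative factor `c` (> 0); used when
#'   `mode = "multiplicative"`.
#' @param offset additive offset `a` (pA or intensity units); used when
#'   `mode = "additive"`.
#' @return an object of class `scaling_transform`.
#' @export
scaling_transform <- function(mode = c("none", "multiplicative", "additive"),
                              factor = 1, offset = 0) {
  mode <- match.arg(mode)
  if (mode == "multiplicative" && (!is_number(factor) || factor <= 0))
    stopf("multiplicative factor must be > 0")
  if (mode == "additive" && !is_number(offset))
    stopf("additive offset must be a finite number")
  structure(list(mode = mode, factor = factor, offset = offset),
            class = "scaling_transform")
}

#' @export
print.scaling_transform <- function(x, ...) {
  cat(switch(x$mode,
             none = "Scaling transform: identity\n",
             multiplicative = sprintf("Scaling transform: x %.4g\n", x$factor),
             additive = sprintf("Scaling transform: + %.4g\n", x$offset)))
  invisible(x)
}

#' Apply a scaling transform to a vector of amplitudes
#'
#' @param amplitudes numeric vector of positive amplitudes (pA) or
#'   intensities (AU).
#' @param transform a [scaling_transform()].
#' @return transformed vector, order preserved.
#' @examples
#' apply_scaling(c(5, 10, 20), scaling_transform("multiplicative", factor = 2))
#' @export
apply_scaling <- function(amplitudes, transform) {
  stopifnot(inherits(transform, "scaling_transform"))
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0))
    stopf("amplitudes must be positive and finite")
  switch(transform$mode,
         none = amplitudes,
         multiplicative = amplitudes * transform$factor,
         additive = amplitudes + transform$offset)
}

#' Sample per-cell mEPSC amplitude populations
#'
#' Draws `events_per_cell` amplitudes for each of `n_cells` cells from an
#' [amplitude_model()]. Each cell receives a log-normal multiplicative
#' factor with unit mean and CV `cell_cv`; draws below the detection floor
#' are rejected and redrawn (truncated sampling), so every emitted amplitude
#' is at least `detection_floor`.
#'
#' @param model an [amplitude_model()].
#' @param n_cells number of cells (>= 1).
#' @param events_per_cell number of events per cell (>= 1).
#' @param seed optional integer seed; identical seeds give identical output.
#' @param condition label attached to the sample (e.g. `"vehicle"`).
#' @param max_rounds maximum number of redraw rounds before declaring the
#'   truncation infeasible.
#' @return a named list of numeric vectors (one per cell), class
#'   `cell_amplitudes`, with the model, condition and seed as attributes.
#' @examples
#' cells <- sample_cell_amplitudes(amplitude_model(), 5, 150, seed = 1)
#' sapply(cells, min) # all >= 5 pA
#' @export
sample_cell_amplitudes <- function(model, n_cells, events_per_cell,
                                   seed = NULL, condition = "control",
                                   max_rounds = 1000L) {
  stopifnot(inherits(model, "amplitude_model"))
  if (!is_count(n_cells)) stopf("n_cells must be a positive integer")
  if (!is_count(events_per_cell))
    stopf("events_per_cell must be a positive integer")
  cells <- with_seed_if(seed, {
    lapply(seq_len(n_cells), function(i) {
      cell_factor <- if (model$cell_cv > 0) {
        s2 <- log(1 + model$cell_cv^2)
        rlnorm(1, meanlog = -s2 / 2, sdlog = sqrt(s2))
      } else 1
      draw_truncated(model, cell_factor, events_per_cell, max_rounds)
    })
  })
  names(cells) <- sprintf("cell%02d", seq_len(n_cells))
  structure(cells, class = "cell_amplitudes",
            model = model, condition = condition, seed = seed)
}

# Rejection sampling of `n` amplitudes >= detection_floor for one cell.
draw_truncated <- function(model, cell_factor, n, max_rounds) {
  out <- numeric(0)
  for (round in seq_len(max_rounds)) {
    need <- n - length(out)
    if (need == 0L) break
    a <- cell_factor * rlnorm(max(need, 16L), model$mu_log, model$sigma_log)
    if (model$sigma_log == 0 && any(a < model$detection_floor))
      stopf("detection floor %.3g pA lies above the degenerate amplitude %.3g pA",
            model$detection_floor, a[1])
    a <- a[a >= model$detection_floor]
    out <- c(out, a[seq_len(min(length(a), need))])
  }
  if (length(out) < n)
    stopf("truncated sampling infeasible: detection floor %.3g pA rejects essentially all draws",
          model$detection_floor)
  out
}

#' @export
print.cell_amplitudes <- function(x, ...) {
  n <- lengths(x)
  cat(sprintf("Per-cell amplitudes: %d cells, %d-%d events/cell (%s)\n",
              length(x), min(n), max(n),
              attr(x, "condition") %||% "unlabelled"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an event table to a per-cell amplitude list
#'
#' @param events data frame with columns `cell_id` and `amp_pA` (the layout
#'   written by [write_events_csv()]).
#' @param condition optional condition label to filter on, when the table
#'   has a `condition` column.
#' @return a `cell_amplitudes` list.
#' @export
as_cell_amplitudes <- function(events, condition = NULL) {
  stopifnot(is.data.frame(events),
            all(c("cell_id", "amp_pA") %in% names(events)))
  if (!is.null(condition) && "condition" %in% names(events))
    events <- events[events$condition == condition, , drop = FALSE]
  if (nrow(events) == 0) stopf("no events after filtering")
  cells <- split(events$amp_pA, events$cell_id)
  structure(cells, class = "cell_amplitudes",
            condition = condition %||% "unlabelled")
}
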