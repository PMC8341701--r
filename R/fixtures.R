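#' Anchor pO2 values of the four measured regions of interest
#'
#' The published maximum/initial mean pO2 of the four EPR voxels the model is
#' matched against. Only these anchors are public; full 9-point series are
#' generated synthetically with [make_roi_series()].
#'
#' @return A tibble with `label` and `anchor_po2` (mmHg).
#' @export
roi_anchors <- function() {
  tibble::tibble(label = c("ROI1", "ROI2", "ROI3", "ROI4"),
                 anchor_po2 = c(36.312, 22.89, 13.99, 1.83))
}

#' Synthetic ROI-like pO2 time series
#'
#' Generates a 9-point mean-pO2 series at t = 4, 7, ..., 28 minutes standing
#' in for an unpublished experimental voxel series. Styles:
#' `flat` repeats the anchor; `drop_recover` holds the anchor, dips by the
#' full amplitude mid-series and recovers (emulating the large fast
#' fluctuations seen in well-oxygenated voxels); `oscillate` superimposes a
#' sinusoid of half-amplitude; `random_walk` takes seeded Gaussian steps of
#' sd `amplitude/3`. All values are clipped to `[0, anchor + amplitude]`.
#'
#' @param anchor_po2 Anchor level (mmHg), the series start.
#' @param style One of `"flat"`, `"drop_recover"`, `"oscillate"`,
#'   `"random_walk"`.
#' @param amplitude Fluctuation amplitude (mmHg).
#' @param seed RNG seed (used by the stochastic styles).
#' @param label Optional label stored as an attribute.
#' @return A tibble `t_min`, `po2_mmHg` with attributes `anchor`, `style`,
#'   `amplitude`, `seed`, `clipped`, `label`.
#' @examples
#' make_roi_series(36.312, "drop_recover", amplitude = 30)
#' @export
make_roi_series <- function(anchor_po2, style = c("flat", "drop_recover",
                                                  "oscillate", "random_walk"),
                            amplitude = 0, seed = 1L, label = NULL) {
  style <- match.arg(style)
  stopifnot(anchor_po2 >= 0, amplitude >= 0)
  t_min <- schedule_boundaries()[-1]
  n <- length(t_min)
  raw <- switch(style,
    flat = rep(anchor_po2, n),
    drop_recover = anchor_po2 - amplitude * c(0, 0, 0.5, 1, 1, 0.6, 0.3, 0.1, 0),
    oscillate = anchor_po2 + amplitude / 2 * sin(2 * pi * seq_len(n) / 4.5),
    random_walk = withr::with_seed(as.integer(seed), {
      anchor_po2 + cumsum(c(0, stats::rnorm(n - 1, 0, amplitude / 3)))
    }))
  hi <- anchor_po2 + amplitude
  vals <- pmin(pmax(raw, 0), hi)
  out <- tibble::tibble(t_min = t_min, po2_mmHg = vals)
  attr(out, "anchor") <- anchor_po2
  attr(out, "style") <- style
  attr(out, "amplitude") <- amplitude
  attr(out, "seed") <- as.integer(seed)
  attr(out, "clipped") <- any(raw != vals)
  attr(out, "label") <- label
  out
}

#' Ground-truth schedule/series pair for recovery testing
#'
#' Forward-simulates a known schedule from a tissue's steady state and returns
#' the resulting series together with the schedule that generated it. Fitting
#' the returned series should recover the simulated dynamics (the recovery
#' closure used by the self-consistency tests).
#'
#' @param layout A relaxed tissue.
#' @param field Its stabilized `oxygen_field`.
#' @param true_schedule The generating `ox_schedule`.
#' @param params Model parameters.
#' @return A list `series` (tibble with anchor attribute) and `schedule`.
#' @export
forward_series <- function(layout, field, true_schedule, params = ox_params()) {
  sim <- if (true_schedule$kind == "influx") {
    simulate_schedule(field, layout, influx_schedule = true_schedule,
                      params = params)
  } else {
    simulate_schedule(field, layout, uptake_schedule = true_schedule,
                      params = params)
  }
  attr(sim, "anchor") <- average_po2(field)
  list(series = sim, schedule = true_schedule)
}
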