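#' Apply a fixed schedule to a library entry and score the fit
#'
#' Regenerates (or accepts) the entry's tissue, stabilizes its own steady
#' state, simulates the fluctuation protocol under the given schedule exactly
#' as fitted (no re-optimization), and returns the goodness of fit against
#' the measured series.
#'
#' @param entry A one-row `tissue_library` slice, or a `tissue_layout`.
#' @param schedule An `ox_schedule` (influx or uptake).
#' @param roi The measured series (tibble `t_min`, `po2_mmHg`).
#' @param params Model parameters.
#' @param gof_form See [goodness_of_fit()].
#' @return A list: `gof`, `simulated` tibble, and `stabilized_po2`.
#' @export
evaluate_schedule <- function(entry, schedule, roi, params = ox_params(),
                              gof_form = c("relative", "mean_square")) {
  gof_form <- match.arg(gof_form)
  lay <- if (inherits(entry, "tissue_layout")) {
    entry
  } else if ("layout" %in% names(entry) && !is.null(entry$layout[[1]])) {
    entry$layout[[1]]
  } else {
    entry_layout(entry, params)
  }
  masks <- indicator_masks(lay, params)
  st <- stabilize_oxygen(lay, params, masks = masks)
  sim <- if (schedule$kind == "influx") {
    simulate_schedule(st$field, lay, influx_schedule = schedule,
                      params = params, masks = masks)
  } else {
    simulate_schedule(st$field, lay, uptake_schedule = schedule,
                      params = params, masks = masks)
  }
  list(gof = goodness_of_fit(roi, sim, gof_form), simulated = sim,
       stabilized_po2 = st$report$average_po2)
}

#' Robustness of a fitted schedule across representative tissues
#'
#' Applies one fitted schedule verbatim to every tissue in a representative
#' set and counts how many reproduce the measured series with a goodness of
#' fit below the threshold. The per-tissue table backs the deviation-vs-GoF
#' scatter (deviation = stabilized pO2 minus the series anchor).
#'
#' @param representatives A `tissue_library` subset (see
#'   [select_representatives()]).
#' @param schedule The fitted `ox_schedule`.
#' @param roi The measured series the schedule was fitted to; its anchor is
#'   taken from the `anchor` attribute if present, else the series maximum.
#' @param threshold Pass when `gof < threshold`.
#' @param params Model parameters.
#' @param gof_form See [goodness_of_fit()].
#' @return A list of class `robustness_report`: `summary` (one-row tibble
#'   with `kind`, `n_representatives`, `n_pass`, `threshold`) and
#'   `per_tissue` (composition, stabilized pO2, deviation, gof, pass).
#' @export
robustness_counts <- function(representatives, schedule, roi, threshold = 0.2,
                              params = ox_params(),
                              gof_form = c("relative", "mean_square")) {
  gof_form <- match.arg(gof_form)
  anchor <- attr(roi, "anchor") %||% max(series_values(roi))
  n <- nrow(representatives)
  gof <- stab <- numeric(n)
  for (i in seq_len(n)) {
    ev <- evaluate_schedule(representatives[i, ], schedule, roi, params, gof_form)
    gof[i] <- ev$gof
    stab[i] <- ev$stabilized_po2
  }
  per <- tibble::tibble(
    composition_index = representatives$composition_index,
    vascular = representatives$vascular, tumor = representatives$tumor,
    stromal = representatives$stromal,
    stabilized_po2 = stab, deviation_mmHg = stab - anchor,
    gof = gof, pass = gof < threshold)
  structure(list(
    summary = tibble::tibble(kind = schedule$kind, n_representatives = n,
                             n_pass = sum(per$pass), threshold = threshold,
                             anchor_po2 = anchor),
    per_tissue = per), class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<robustness_report> %s schedule: %d / %d tissues with GoF < %g\n",
              s$kind, s$n_pass, s$n_representatives, s$threshold))
  invisible(x)
}
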