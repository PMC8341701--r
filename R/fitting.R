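#' Piecewise-constant rate schedule
#'
#' A vascular influx or tumor uptake schedule over the nine fluctuation
#' segments 0-4, 4-7, ..., 25-28 minutes.
#'
#' @param kind `"influx"` (rates in `[0, 1]`) or `"uptake"` (rates in `[0, 50]`).
#' @param rates Numeric vector of 9 segment rates.
#' @param params Model parameters supplying the rate bounds.
#' @return An object of class `ox_schedule`.
#' @examples
#' new_schedule("influx", rep(1, 9))
#' @export
new_schedule <- function(kind = c("influx", "uptake"), rates,
                         params = ox_params()) {
  kind <- match.arg(kind)
  s <- structure(list(kind = kind, boundaries = schedule_boundaries(),
                      rates = as.numeric(rates)), class = "ox_schedule")
  validate_schedule(s, kind, params)
  s
}

validate_schedule <- function(s, kind, params) {
  if (!inherits(s, "ox_schedule")) stop("not an `ox_schedule`", call. = FALSE)
  if (!identical(s$kind, kind))
    stop(sprintf("expected an %s schedule, got %s", kind, s$kind), call. = FALSE)
  if (length(s$rates) != length(schedule_boundaries()) - 1)
    stop("schedule must have one rate per segment (9)", call. = FALSE)
  hi <- if (kind == "influx") params$influx_max else params$uptake_max
  if (any(!is.finite(s$rates)) || any(s$rates < 0) || any(s$rates > hi))
    stop(sprintf("%s rates must lie in [0, %g]", kind, hi), call. = FALSE)
  invisible(s)
}

#' @export
print.ox_schedule <- function(x, ...) {
  cat(sprintf("<ox_schedule> %s: %s\n", x$kind,
              paste(signif(x$rates, 4), collapse = ", ")))
  invisible(x)
}

#' Per-time-point objective term
#'
#' Absolute difference between an experimental and a simulated average pO2
#' value; the fitting objective sums these over the series.
#'
#' @param gamma_E,gamma_C Measured and simulated mean pO2 (mmHg).
#' @return `|gamma_E - gamma_C|` (mmHg).
#' @export
objective_term <- function(gamma_E, gamma_C) abs(gamma_E - gamma_C)

#' Goodness of fit between two pO2 series
#'
#' Default (`"relative"`): the Euclidean norm of the residual divided by the
#' Euclidean norm of the measured series, a dimensionless relative error
#' (0 for identical series, 1 when the simulation is uniformly zero).
#' `"mean_square"`: the per-point mean of squared residuals (mmHg^2). When the
#' measured series is all zero, the relative form falls back to the absolute
#' root-mean-square residual.
#'
#' @param series_E,series_opt Numeric vectors of equal length (mmHg), or
#'   tibbles with a `po2_mmHg` column.
#' @param form `"relative"` or `"mean_square"`.
#' @return A single non-negative number.
#' @examples
#' goodness_of_fit(c(10, 10), c(11, 9)) # sqrt(2)/sqrt(200) = 0.1
#' @export
goodness_of_fit <- function(series_E, series_opt,
                            form = c("relative", "mean_square")) {
  form <- match.arg(form)
  e <- series_values(series_E)
  o <- series_values(series_opt)
  if (length(e) != length(o)) stop("series lengths differ", call. = FALSE)
  if (form == "mean_square") return(mean((e - o)^2))
  den <- sqrt(sum(e^2))
  if (den == 0) return(sqrt(mean((e - o)^2)))
  sqrt(sum((e - o)^2)) / den
}

series_values <- function(x) {
  if (is.data.frame(x)) {
    if (!"po2_mmHg" %in% names(x)) stop("series tibble needs a `po2_mmHg` column",
                                        call. = FALSE)
    return(as.numeric(x$po2_mmHg))
  }
  as.numeric(x)
}

#' Pattern-search options
#'
#' Controls for the one-dimensional mesh-adaptive search used per segment.
#' Defaults: initial mesh 0.25 (influx) or 12.5 (uptake), minimum mesh equal
#' to the rate range divided by 4096 (dyadic refinement), endpoint tolerance
#' 0.01 mmHg.
#'
#' @param initial_mesh,mesh_min Mesh sizes in rate units (NULL = kind default).
#' @param fit_tol Stop a segment search when the endpoint is within this many
#'   mmHg of its target.
#' @param max_evals Safety cap on objective evaluations per segment.
#' @return A list of class `search_options`.
#' @export
search_options <- function(initial_mesh = NULL, mesh_min = NULL,
                           fit_tol = 0.01, max_evals = 500L) {
  structure(list(initial_mesh = initial_mesh, mesh_min = mesh_min,
                 fit_tol = fit_tol, max_evals = as.integer(max_evals)),
            class = "search_options")
}

resolve_search <- function(opts, kind, params) {
  hi <- if (kind == "influx") params$influx_max else params$uptake_max
  list(initial_mesh = opts$initial_mesh %||% (hi / 4),
       mesh_min = opts$mesh_min %||% (hi / 4096),
       fit_tol = opts$fit_tol, max_evals = opts$max_evals, hi = hi)
}

# Simulate one fluctuation segment at given rates from a fixed start field.
run_segment <- function(vals, masks, seg, delta_V, delta_T, params) {
  co <- step_coefficients(masks, delta_V, delta_T, params)
  res <- ox_run_cpp(vals, co$src, co$upt,
                    params$D * params$dt / params$dx^2, params$kappa_m,
                    segment_steps(seg, params), FALSE, 0, FALSE, 0L,
                    co$clamp_idx, co$clamp_value)
  res
}

#' Fit a single segment's rate by pattern search
#'
#' One-dimensional mesh-adaptive direct search over the segment's rate: the
#' poll starts at `start_rate`, evaluates `rate +/- mesh` (projected onto the
#' bounds), doubles the mesh on an improving poll and halves it otherwise,
#' stopping when the mesh falls below `mesh_min` or the simulated segment
#' endpoint is within `fit_tol` mmHg of the target. The objective of a poll
#' is the absolute endpoint error; a diverged simulation scores +Inf.
#'
#' @param field Oxygen field at the start of the segment (an `oxygen_field`
#'   or bare matrix).
#' @param layout The tissue (used only if `masks` is missing).
#' @param segment Segment index 1..9.
#' @param target_value Measured mean pO2 (mmHg) at the segment's end.
#' @param mode `"influx"` or `"uptake"`.
#' @param params Model parameters.
#' @param search_opts See [search_options()].
#' @param start_rate Initial poll center (the previous segment's accepted
#'   rate; 1 for the first segment).
#' @param masks Optional precomputed masks.
#' @return A list: `rate`, `endpoint` (simulated mean pO2), `error` (mmHg),
#'   `end_field` (matrix at the segment's end under `rate`), `trace` tibble
#'   of all polls, and `evals`.
#' @export
fit_segment <- function(field, layout, segment, target_value,
                        mode = c("influx", "uptake"), params = ox_params(),
                        search_opts = search_options(), start_rate = 1,
                        masks = NULL) {
  mode <- match.arg(mode)
  if (is.null(masks)) masks <- indicator_masks(layout, params)
  so <- resolve_search(search_opts, mode, params)
  vals <- if (inherits(field, "oxygen_field")) field$values else field
  rates_of <- function(r) if (mode == "influx") c(r, 1) else c(1, r)

  cache <- new.env(parent = emptyenv())
  evals <- 0L
  tr_rate <- numeric(0); tr_err <- numeric(0); tr_mesh <- numeric(0)
  eval_rate <- function(r, mesh) {
    key <- sprintf("%.12g", r)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rv <- rates_of(r)
    res <- tryCatch(run_segment(vals, masks, segment, rv[1], rv[2], params),
                    error = function(e) NULL)
    out <- if (is.null(res) || res$diverged) {
      list(err = Inf, avg = NA_real_, field = NULL)
    } else list(err = objective_term(target_value, res$average),
                avg = res$average, field = res$field)
    evals <<- evals + 1L
    tr_rate[evals] <<- r; tr_err[evals] <<- out$err; tr_mesh[evals] <<- mesh
    cache[[key]] <- out
    out
  }

  proj <- function(r) min(max(r, 0), so$hi)
  best_r <- proj(start_rate)
  best <- eval_rate(best_r, so$initial_mesh)
  mesh <- so$initial_mesh
  while (mesh >= so$mesh_min && best$err >= so$fit_tol && evals < so$max_evals) {
    cand <- unique(c(proj(best_r + mesh), proj(best_r - mesh)))
    cand <- setdiff(cand, best_r)
    improved <- FALSE
    for (r in cand) {
      o <- eval_rate(r, mesh)
      if (o$err < best$err) { best <- o; best_r <- r; improved <- TRUE }
    }
    mesh <- if (improved) mesh * 2 else mesh / 2
  }
  list(rate = best_r, endpoint = best$avg, error = best$err,
       end_field = best$field,
       trace = tibble::tibble(rate = tr_rate, error = tr_err, mesh = tr_mesh),
       evals = evals)
}

#' Fit a full influx or uptake schedule to a measured pO2 series
#'
#' Fits the nine segment rates sequentially in time order: each segment's
#' endpoint depends only on the state inherited from the previous segments
#' and its own rate, so the separable objective is minimized greedily, one
#' pattern search per segment (the first segment starts its poll at rate 1,
#' later segments at the previously accepted rate). During influx fitting the
#' uptake rate stays at 1, and vice versa.
#'
#' @param field The stabilized `oxygen_field` of `layout` (the delta_V = 1,
#'   delta_T = 1 steady state).
#' @param layout The tissue.
#' @param roi A measured series: tibble with `t_min`, `po2_mmHg` (9 rows).
#' @param mode `"influx"` or `"uptake"`.
#' @param params Model parameters.
#' @param search_opts See [search_options()].
#' @param gof_form Goodness-of-fit form reported (see [goodness_of_fit()]).
#' @return An object of class `schedule_fit`: `schedule` (an `ox_schedule`),
#'   `simulated` tibble, `gof`, `gof_form`, `target`, `segments` (per-segment
#'   results incl. poll traces).
#' @export
fit_schedule <- function(field, layout, roi, mode = c("influx", "uptake"),
                         params = ox_params(), search_opts = search_options(),
                         gof_form = c("relative", "mean_square")) {
  mode <- match.arg(mode)
  gof_form <- match.arg(gof_form)
  target <- series_values(roi)
  nseg <- length(schedule_boundaries()) - 1
  if (length(target) != nseg)
    stop("the measured series must have 9 points (t = 4, 7, ..., 28 min)",
         call. = FALSE)
  masks <- indicator_masks(layout, params)
  vals <- if (inherits(field, "oxygen_field")) field$values else field

  rates <- numeric(nseg)
  endpoints <- numeric(nseg)
  segs <- vector("list", nseg)
  prev_rate <- 1
  for (k in seq_len(nseg)) {
    fs <- fit_segment(vals, layout, k, target[k], mode, params, search_opts,
                      start_rate = prev_rate, masks = masks)
    if (is.null(fs$end_field))
      stop("segment ", k, ": all polls diverged", call. = FALSE)
    rates[k] <- fs$rate
    endpoints[k] <- fs$endpoint
    segs[[k]] <- fs[c("rate", "endpoint", "error", "trace", "evals")]
    vals <- fs$end_field
    prev_rate <- fs$rate
  }
  sim <- tibble::tibble(t_min = schedule_boundaries()[-1], po2_mmHg = endpoints)
  structure(list(schedule = new_schedule(mode, rates, params),
                 simulated = sim,
                 gof = goodness_of_fit(target, endpoints, gof_form),
                 gof_form = gof_form,
                 target = tibble::tibble(t_min = schedule_boundaries()[-1],
                                         po2_mmHg = target),
                 segments = segs),
            class = "schedule_fit")
}

#' @export
print.schedule_fit <- function(x, ...) {
  cat(sprintf("<schedule_fit> %s schedule, GoF (%s) = %.4g\n",
              x$schedule$kind, x$gof_form, x$gof))
  cat("  rates:", paste(signif(x$schedule$rates, 4), collapse = ", "), "\n")
  invisible(x)
}
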