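#' Indicator masks coupling discrete elements to the oxygen grid
#'
#' For each grid node, counts the vessels, tumor cells and stromal cells whose
#' center lies strictly within the interaction radius of that node (the
#' indicator function chi_R). A node may be covered by several elements; the
#' counts sum.
#'
#' @param layout A (preferably relaxed) `tissue_layout`.
#' @param params Model parameters.
#' @return A list of class `indicator_masks` with integer matrices `vessel`,
#'   `tumor`, `stromal` (rows = y nodes, columns = x nodes).
#' @examples
#' lay <- relax_layout(sample_layout(tissue_composition(1, 10, 10),
#'                                   ox_params(), seed = 1))
#' m <- indicator_masks(lay, ox_params())
#' sum(m$vessel > 0)
#' @export
indicator_masks <- function(layout, params = ox_params()) {
  g <- grid_nodes(params)
  one <- function(type, R) {
    sub <- layout[layout$type == type, ]
    cover_counts_cpp(sub$x_um, sub$y_um, R, g$nrow, g$ncol,
                     g$x[1], g$y[1], params$dx)
  }
  structure(list(vessel = one("vessel", params$R_V),
                 tumor = one("tumor", params$R_T),
                 stromal = one("stromal", params$R_S),
                 dim = c(g$nrow, g$ncol)),
            class = "indicator_masks")
}

new_field <- function(values, params) {
  structure(list(values = values, dx = params$dx, domain = params$domain),
            class = "oxygen_field")
}

#' Whole-domain average oxygen level
#'
#' Arithmetic mean of the field over all grid nodes, in mmHg.
#'
#' @param field An `oxygen_field` (or a bare numeric matrix).
#' @return A single number (mmHg).
#' @export
average_po2 <- function(field) {
  v <- if (inherits(field, "oxygen_field")) field$values else field
  mean(v)
}

# dt-premultiplied source and uptake coefficient matrices for the solver.
step_coefficients <- function(masks, delta_V, delta_T, params) {
  if (delta_V < 0 || delta_V > params$influx_max)
    stop(sprintf("delta_V must lie in [0, %g]", params$influx_max), call. = FALSE)
  if (delta_T < 0 || delta_T > params$uptake_max)
    stop(sprintf("delta_T must lie in [0, %g]", params$uptake_max), call. = FALSE)
  if (identical(params$vessel_mode, "clamp")) {
    list(src = matrix(0, masks$dim[1], masks$dim[2]),
         upt = params$dt * params$uptake_scale *
           (delta_T * params$T_max * masks$tumor + params$S_max * masks$stromal),
         clamp_idx = which(masks$vessel > 0) - 1L,
         clamp_value = delta_V * params$gamma_max)
  } else {
    list(src = params$dt * delta_V * params$gamma_max * masks$vessel,
         upt = params$dt * params$uptake_scale *
           (delta_T * params$T_max * masks$tumor + params$S_max * masks$stromal),
         clamp_idx = integer(0), clamp_value = 0)
  }
}

#' One forward-Euler step of the oxygen equation
#'
#' Advances the reaction-diffusion equation by a single time step `dt` using
#' the 5-point Laplacian with zero-flux boundaries: vascular influx adds
#' `delta_V * gamma_max` per covering vessel per node per second; cellular
#' uptake removes `(delta_T*T_max*n_tumor + S_max*n_stromal) * uptake_scale *
#' gamma/(kappa_m+gamma)` per node per second. The result is clipped at 0.
#'
#' @param field An `oxygen_field`.
#' @param masks Masks from [indicator_masks()].
#' @param delta_V Vascular influx rate in `[0, 1]`.
#' @param delta_T Tumor uptake rate in `[0, 50]`.
#' @param params Model parameters.
#' @return The advanced `oxygen_field`.
#' @export
step_oxygen <- function(field, masks, delta_V = 1, delta_T = 1,
                        params = ox_params()) {
  co <- step_coefficients(masks, delta_V, delta_T, params)
  res <- ox_run_cpp(field$values, co$src, co$upt,
                    params$D * params$dt / params$dx^2, params$kappa_m,
                    1L, FALSE, 0, FALSE, 0L, co$clamp_idx, co$clamp_value)
  if (res$diverged) stop("oxygen solver diverged (non-finite values)", call. = FALSE)
  new_field(res$field, params)
}

#' Stabilize the oxygen field of a tissue
#'
#' Runs the explicit solver from a uniform initial level until the normalized
#' per-step error drops to `params$eps_tol` (default 1e-10) or `params$max_steps`
#' is reached. Stabilization uses the reference rates `delta_V`, `delta_T`
#' (both 1 by default: full vascular supply, base tumor uptake).
#'
#' @param layout A relaxed `tissue_layout`.
#' @param params Model parameters.
#' @param init Initial uniform oxygen level (mmHg).
#' @param delta_V,delta_T Rates held fixed during stabilization.
#' @param masks Optional precomputed [indicator_masks()].
#' @param trace_every Record the running average every this many steps
#'   (0 disables).
#' @return A list with `field` (the stabilized `oxygen_field`) and `report`,
#'   a one-row tibble: `iterations`, `final_error`, `average_po2`, `converged`.
#' @examples
#' \donttest{
#' p <- ox_params(domain = c(-150, 150, -150, 150))
#' lay <- relax_layout(sample_layout(tissue_composition(3.5, 55, 30), p, 1), p)
#' st <- stabilize_oxygen(lay, p)
#' st$report
#' }
#' @export
stabilize_oxygen <- function(layout, params = ox_params(), init = 0,
                             delta_V = 1, delta_T = 1, masks = NULL,
                             trace_every = 0L) {
  if (is.null(masks)) masks <- indicator_masks(layout, params)
  n_cells <- sum(layout$type != "vessel")
  n_ves <- sum(layout$type == "vessel")
  if (n_cells == 0 && n_ves > 0 && delta_V > 0)
    stop("layout has vessels but no cells: constant influx cannot stabilize",
         call. = FALSE)
  g <- grid_nodes(params)
  co <- step_coefficients(masks, delta_V, delta_T, params)
  res <- ox_run_cpp(matrix(init, g$nrow, g$ncol), co$src, co$upt,
                    params$D * params$dt / params$dx^2, params$kappa_m,
                    params$max_steps, TRUE, params$eps_tol,
                    identical(params$error_norm, "sum_of_squares"),
                    as.integer(trace_every), co$clamp_idx, co$clamp_value)
  if (res$diverged) stop("oxygen solver diverged (non-finite values)", call. = FALSE)
  list(field = new_field(res$field, params),
       report = tibble::tibble(iterations = res$steps,
                               final_error = res$eps,
                               average_po2 = res$average,
                               converged = res$converged),
       trace = tibble::as_tibble(res$trace))
}

# segment boundaries (min) of the fluctuation protocol
schedule_boundaries <- function() c(0, 4, 7, 10, 13, 16, 19, 22, 25, 28)

#' Simulate oxygen fluctuations under piecewise-constant rate schedules
#'
#' Starting from a stabilized field, applies a piecewise-constant vascular
#' influx or tumor uptake schedule over the segments 0-4, 4-7, ..., 25-28
#' minutes and records the whole-domain average at the end of each segment
#' (t = 4, 7, ..., 28 min). Whichever rate is not scheduled is held at 1.
#'
#' @param field The stabilized `oxygen_field` of `layout`.
#' @param layout The tissue the field belongs to.
#' @param influx_schedule,uptake_schedule At most one [new_schedule()]; the
#'   other mechanism keeps its reference rate.
#' @param params Model parameters.
#' @param masks Optional precomputed masks.
#' @return A tibble with `t_min` (9 values) and `po2_mmHg`.
#' @export
simulate_schedule <- function(field, layout, influx_schedule = NULL,
                              uptake_schedule = NULL, params = ox_params(),
                              masks = NULL) {
  if (!is.null(influx_schedule) && !is.null(uptake_schedule))
    stop("vary exactly one schedule; the other rate is fixed at 1", call. = FALSE)
  if (is.null(masks)) masks <- indicator_masks(layout, params)
  bounds <- schedule_boundaries()
  nseg <- length(bounds) - 1
  dV <- rep(1, nseg); dT <- rep(1, nseg)
  if (!is.null(influx_schedule)) {
    validate_schedule(influx_schedule, "influx", params)
    dV <- influx_schedule$rates
  }
  if (!is.null(uptake_schedule)) {
    validate_schedule(uptake_schedule, "uptake", params)
    dT <- uptake_schedule$rates
  }
  vals <- field$values
  out <- numeric(nseg)
  for (k in seq_len(nseg)) {
    steps <- segment_steps(k, params)
    co <- step_coefficients(masks, dV[k], dT[k], params)
    res <- ox_run_cpp(vals, co$src, co$upt,
                      params$D * params$dt / params$dx^2, params$kappa_m,
                      steps, FALSE, 0, FALSE, 0L, co$clamp_idx, co$clamp_value)
    if (res$diverged) stop("oxygen solver diverged during segment ", k, call. = FALSE)
    vals <- res$field
    out[k] <- res$average
  }
  tibble::tibble(t_min = bounds[-1], po2_mmHg = out)
}

segment_steps <- function(k, params) {
  bounds <- schedule_boundaries()
  as.integer(round((bounds[k + 1] - bounds[k]) * 60 / params$dt))
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf("<oxygen_field> %d x %d nodes, dx = %g um, mean pO2 %.2f mmHg\n",
              nrow(x$values), ncol(x$values), x$dx, mean(x$values)))
  invisible(x)
}
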