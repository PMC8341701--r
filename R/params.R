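#' Model parameters for the voxel tissue simulator
#'
#' Returns the full set of physical and computational parameters governing the
#' tissue patch and its oxygen dynamics. Defaults describe a 1 mm^2 patch, the
#' cross-section of a typical EPR-imaging voxel. One model concentration unit
#' corresponds to 1 mmHg of oxygen partial pressure.
#'
#' @param R_T Tumor cell radius (um).
#' @param R_S Stromal cell radius (um).
#' @param R_V Vessel radius (um).
#' @param stiffness Repulsive spring stiffness F (ug/(um s^2)).
#' @param nu Viscosity of the medium (ug/(um s)); sets the overdamped mobility.
#' @param D Oxygen diffusion coefficient (um^2/s).
#' @param gamma_max Intravascular oxygen level (model units, = mmHg).
#' @param kappa_m Michaelis constant of cellular uptake (model units).
#' @param T_max Tumor cell base uptake rate (model units/s per covering cell
#'   at a node, before `uptake_scale`).
#' @param S_max Stromal cell base uptake rate (same units as `T_max`).
#' @param uptake_scale Dimensionless nodal uptake scale applied to both
#'   `T_max` and `S_max`. It bridges the per-cell-volume uptake units to
#'   per-node concentration units on the grid and is calibrated once so that
#'   the reference composition (3.5% vascular, 55% tumor, 30% stromal)
#'   stabilizes near 29.9 mmHg; see the methods vignette.
#' @param dx Grid width (um).
#' @param dt Time step of the oxygen solver (s).
#' @param domain Rectangle bounds `c(xmin, xmax, ymin, ymax)` (um).
#' @param sigma_g Mass scaling constant (g); documentation of the
#'   concentration unit only, never used in computation.
#' @param influx_max Upper bound of the vascular influx rate \eqn{\delta_V}.
#' @param uptake_max Upper bound of the tumor uptake rate \eqn{\delta_T}.
#' @param vessel_mode How vessels feed the grid. `"source"` (default) adds
#'   `delta_V * gamma_max` per covering vessel per node per second as a
#'   constant-rate source, the reading under which the published steady-state
#'   statistics are reproduced best. `"clamp"` instead holds vessel-covered
#'   nodes at the intravascular level `delta_V * gamma_max` (a
#'   local-reservoir alternative kept as a configuration switch; see the
#'   methods vignette).
#' @param eps_tol Stabilization threshold on the normalized per-step error.
#' @param max_steps Iteration cap of the stabilization loop.
#' @param error_norm `"euclidean"` uses sqrt(sum of squared per-step changes)
#'   normalized by the node count; `"sum_of_squares"` omits the square root.
#' @param dt_relax Euler step (s) of the overlap relaxation.
#' @param tol_disp Relaxation stops when the max per-step displacement (um)
#'   falls below this.
#' @param relax_max_iter Relaxation iteration cap.
#' @param overlap_tol Pairwise overlaps below this depth (um) are ignored
#'   when counting residual overlaps (contact tolerance; 0.05 um is under 1%
#'   of the smallest cell radius). Squeezed force-balance contacts between
#'   immobile vessels settle at depths an order of magnitude below this.
#' @param stall_window Relaxation iterations without displacement improvement
#'   after which a still-overlapping layout is declared jammed.
#'
#' @return A list of class `ox_params`.
#' @examples
#' p <- ox_params()
#' p$D * p$dt / p$dx^2 # diffusion stability number, must be <= 1/4
#' @export
ox_params <- function(R_T = 7.5, R_S = 3.75, R_V = 20,
                      stiffness = 50, nu = 250,
                      D = 100, gamma_max = 60, kappa_m = 134,
                      T_max = 0.382, S_max = 0.382,
                      uptake_scale = 54.5121,
                      dx = 5, dt = 0.05,
                      domain = c(-500, 500, -500, 500),
                      sigma_g = 0.5e-19,
                      influx_max = 1, uptake_max = 50,
                      eps_tol = 1e-10, max_steps = 1e6,
                      vessel_mode = c("source", "clamp"),
                      error_norm = c("euclidean", "sum_of_squares"),
                      dt_relax = 1, tol_disp = 1e-3,
                      relax_max_iter = 1e4, overlap_tol = 0.05,
                      stall_window = 500) {
  error_norm <- match.arg(error_norm)
  vessel_mode <- match.arg(vessel_mode)
  p <- list(R_T = R_T, R_S = R_S, R_V = R_V, stiffness = stiffness, nu = nu,
            D = D, gamma_max = gamma_max, kappa_m = kappa_m,
            T_max = T_max, S_max = S_max, uptake_scale = uptake_scale,
            dx = dx, dt = dt, domain = domain, sigma_g = sigma_g,
            influx_max = influx_max, uptake_max = uptake_max,
            eps_tol = eps_tol, max_steps = as.integer(max_steps),
            vessel_mode = vessel_mode, error_norm = error_norm,
            dt_relax = dt_relax, tol_disp = tol_disp,
            relax_max_iter = as.integer(relax_max_iter),
            overlap_tol = overlap_tol, stall_window = as.integer(stall_window))
  validate_params(p)
  structure(p, class = "ox_params")
}

validate_params <- function(p) {
  num <- c("R_T", "R_S", "R_V", "stiffness", "nu", "D", "gamma_max", "kappa_m",
           "T_max", "S_max", "uptake_scale", "dx", "dt", "sigma_g")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) || p[[f]] <= 0)
      stop("parameter `", f, "` must be a single positive number", call. = FALSE)
  }
  if (length(p$domain) != 4 || p$domain[2] <= p$domain[1] || p$domain[4] <= p$domain[3])
    stop("`domain` must be c(xmin, xmax, ymin, ymax) with positive extents", call. = FALSE)
  cfl <- p$D * p$dt / p$dx^2
  if (cfl > 0.25)
    stop(sprintf("diffusion stability violated: D*dt/dx^2 = %.3g > 1/4", cfl), call. = FALSE)
  invisible(p)
}

#' @export
print.ox_params <- function(x, ...) {
  cat("<ox_params>\n")
  cat(sprintf("  domain %g x %g um, dx = %g um, dt = %g s (D*dt/dx^2 = %.2g)\n",
              diff(x$domain[1:2]), diff(x$domain[3:4]), x$dx, x$dt,
              x$D * x$dt / x$dx^2))
  cat(sprintf("  radii (um): vessel %g, tumor %g, stromal %g\n", x$R_V, x$R_T, x$R_S))
  cat(sprintf("  gamma_max %g, kappa_m %g, T_max = S_max = %g (uptake scale %g)\n",
              x$gamma_max, x$kappa_m, x$T_max, x$uptake_scale))
  invisible(x)
}

# Grid node coordinates spanned by the domain (nodes at domain edges included).
grid_nodes <- function(params) {
  x <- seq(params$domain[1], params$domain[2], by = params$dx)
  y <- seq(params$domain[3], params$domain[4], by = params$dx)
  list(x = x, y = y, nrow = length(y), ncol = length(x))
}

domain_area <- function(params) {
  diff(params$domain[1:2]) * diff(params$domain[3:4])
}

# Deterministic stage/index seed derivation so every stage of the pipeline has
# its own named stream; stays below 2^31.
derive_seed <- function(global_seed, stage, index = 0L) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 131 + ch) %% m
  s <- (as.numeric(global_seed) %% m) * 48271 %% m
  ((s + h * 69621 + as.numeric(index) * 16807) %% (m - 1)) + 1
}
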