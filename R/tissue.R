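#' Tissue composition in area fractions
#'
#' @param vascular,tumor,stromal Percent of the patch area occupied by
#'   vessels, tumor cells and stromal cells. Non-negative; sum at most 100.
#' @return A one-row tibble with columns `vascular`, `tumor`, `stromal`.
#' @examples
#' tissue_composition(3.5, 55, 30)
#' @export
tissue_composition <- function(vascular, tumor, stromal) {
  stopifnot(length(vascular) == length(tumor), length(tumor) == length(stromal))
  if (any(vascular < 0 | tumor < 0 | stromal < 0))
    stop("area fractions must be non-negative", call. = FALSE)
  if (any(vascular + tumor + stromal > 100 + 1e-9))
    stop("vascular + tumor + stromal fractions must not exceed 100%", call. = FALSE)
  tibble::tibble(vascular = as.numeric(vascular), tumor = as.numeric(tumor),
                 stromal = as.numeric(stromal))
}

as_composition <- function(comp) {
  if (is.numeric(comp) && length(comp) == 3)
    return(tissue_composition(comp[[1]], comp[[2]], comp[[3]]))
  if (is.data.frame(comp) && all(c("vascular", "tumor", "stromal") %in% names(comp)))
    return(tissue_composition(comp$vascular[1], comp$tumor[1], comp$stromal[1]))
  stop("`comp` must be a length-3 numeric vector or a tibble with columns vascular/tumor/stromal",
       call. = FALSE)
}

#' Element counts realizing a composition
#'
#' Converts area fractions to element counts using the nominal (unclipped)
#' disk area of each element type: `N = round(fraction/100 * area(domain) /
#' (pi R^2))`.
#'
#' @param comp A composition (see [tissue_composition()]).
#' @param params Model parameters from [ox_params()].
#' @return Named integer vector `c(N_V, N_T, N_S)`.
#' @examples
#' composition_to_counts(tissue_composition(3.5, 55, 30), ox_params())
#' @export
composition_to_counts <- function(comp, params = ox_params()) {
  comp <- as_composition(comp)
  A <- domain_area(params)
  n <- function(frac, R) as.integer(round(frac / 100 * A / (pi * R^2)))
  c(N_V = n(comp$vascular, params$R_V),
    N_T = n(comp$tumor, params$R_T),
    N_S = n(comp$stromal, params$R_S))
}

new_layout <- function(df, comp, seed, relaxed = FALSE, relaxation = NULL) {
  tibble::new_tibble(df, composition = comp, seed = seed, relaxed = relaxed,
                     relaxation = relaxation, class = "tissue_layout")
}

#' Randomly place vessels and cells in the patch
#'
#' Draws i.i.d. uniform center positions over the domain for the element
#' counts implied by `comp`. The returned layout is unrelaxed: cells may
#' overlap each other and the vessels until [relax_layout()] is applied.
#'
#' @inheritParams composition_to_counts
#' @param seed Integer RNG seed; the same seed reproduces the same layout.
#' @return A `tissue_layout` tibble with columns `type` (vessel/tumor/stromal),
#'   `x_um`, `y_um`, `radius_um`; composition, seed and relaxation state are
#'   carried as attributes.
#' @examples
#' lay <- sample_layout(tissue_composition(2, 30, 30), ox_params(), seed = 1)
#' dplyr::count(lay, type)
#' @export
sample_layout <- function(comp, params = ox_params(), seed = 1L) {
  comp <- as_composition(comp)
  n <- composition_to_counts(comp, params)
  if (any(n < 0)) stop("negative element counts", call. = FALSE)
  dom <- params$domain
  df <- withr::with_seed(as.integer(seed), {
    draw <- function(k) list(x = stats::runif(k, dom[1], dom[2]),
                             y = stats::runif(k, dom[3], dom[4]))
    v <- draw(n[["N_V"]]); t <- draw(n[["N_T"]]); s <- draw(n[["N_S"]])
    tibble::tibble(
      type = rep(c("vessel", "tumor", "stromal"), times = n),
      x_um = c(v$x, t$x, s$x),
      y_um = c(v$y, t$y, s$y),
      radius_um = rep(c(params$R_V, params$R_T, params$R_S), times = n))
  })
  new_layout(df, comp, as.integer(seed))
}

#' Repulsive Hookean force between two disks
#'
#' Force on the element at `xi` exerted by the element at `xj`: zero beyond
#' contact, and of magnitude `stiffness * ((Ri + Rj) - d)` directed from `xj`
#' toward `xi` when the centers are closer than the radius sum.
#'
#' @param xi,xj Numeric length-2 centers (um).
#' @param ri,rj Radii (um).
#' @param stiffness Spring stiffness (ug/(um s^2)).
#' @return Length-2 force vector on `xi` (ug um/s^2).
#' @examples
#' pairwise_repulsion(c(5, 0), c(-5, 0), 7.5, 7.5, 50) # (250, 0)
#' @export
pairwise_repulsion <- function(xi, xj, ri, rj, stiffness = ox_params()$stiffness) {
  d <- sqrt(sum((xi - xj)^2))
  if (d >= ri + rj) return(c(0, 0))
  if (d < 1e-12) stop("coincident centers: direction undefined (the relaxer jitters these)",
                      call. = FALSE)
  stiffness * ((ri + rj) - d) * (xi - xj) / d
}

#' Resolve overlaps by overdamped force relaxation
#'
#' Iterates the overdamped relocation equations dX/dt = F/nu for tumor and
#' stromal cells with explicit Euler steps until the maximum per-step
#' displacement falls below `params$tol_disp`, the iteration cap is reached,
#' or progress stalls while overlaps remain (a jammed packing). Vessels never
#' move, and vessel-vessel overlap is permitted by construction. Cells pushed
#' past the domain edge are clamped to the boundary.
#'
#' @param layout A `tissue_layout` (relaxed or not).
#' @param params Model parameters.
#' @param trace_every Record the overlap count, max displacement and overlap
#'   energy every this many iterations (0 disables the trace).
#' @return The layout with updated coordinates; attribute `relaxed` is TRUE
#'   and attribute `relaxation` holds a report with `iterations`,
#'   `n_overlap`, `max_disp`, `converged`, `jammed` and the trace.
#' @examples
#' lay <- sample_layout(tissue_composition(1, 20, 20), ox_params(), seed = 2)
#' rel <- relax_layout(lay)
#' attr(rel, "relaxation")$n_overlap
#' @export
relax_layout <- function(layout, params = ox_params(), trace_every = 25L) {
  stopifnot(inherits(layout, "tissue_layout"))
  dom <- params$domain
  res <- relax_cells_cpp(layout$x_um, layout$y_um, layout$radius_um,
                         layout$type != "vessel",
                         params$stiffness, params$nu, params$dt_relax,
                         params$tol_disp, params$relax_max_iter,
                         dom[1], dom[2], dom[3], dom[4],
                         params$overlap_tol, params$stall_window,
                         as.integer(trace_every),
                         as.integer(derive_seed(attr(layout, "seed") %||% 0, "jitter")))
  out <- layout
  out$x_um <- res$x
  out$y_um <- res$y
  report <- list(iterations = res$iterations, max_disp = res$max_disp,
                 n_overlap = res$n_overlap, overlap_energy = res$overlap_energy,
                 converged = res$converged,
                 jammed = !res$converged && res$n_overlap > 0,
                 trace = tibble::as_tibble(res$trace))
  new_layout(out, attr(layout, "composition"), attr(layout, "seed"),
             relaxed = TRUE, relaxation = report)
}

#' Count residual overlapping pairs in a layout
#'
#' Pairs involving at least one cell whose center distance is more than
#' `tol` below the radius sum. Vessel-vessel pairs are never counted.
#'
#' @inheritParams relax_layout
#' @param tol Overlap depth (um) below which a contact is ignored.
#' @return Integer count of overlapping pairs.
#' @export
count_overlaps <- function(layout, params = ox_params(), tol = params$overlap_tol) {
  mov <- layout$type != "vessel"
  x <- layout$x_um; y <- layout$y_um; r <- layout$radius_um
  n <- nrow(layout)
  if (n < 2) return(0L)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    keep <- mov[i] | mov[j]
    if (!any(keep)) next
    j <- j[keep]
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    cnt <- cnt + sum(d < r[i] + r[j] - tol)
  }
  as.integer(cnt)
}

#' @export
print.tissue_layout <- function(x, ...) {
  comp <- attr(x, "composition")
  cat(sprintf("<tissue_layout> %d elements (%s), seed %s, %s\n",
              nrow(x), paste(sprintf("%s %.1f%%", names(comp), unlist(comp)),
                             collapse = ", "),
              format(attr(x, "seed")),
              if (isTRUE(attr(x, "relaxed"))) "relaxed" else "unrelaxed"))
  NextMethod()
}
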