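# Shared fixtures and independent oracles, all generated in code.

# Small patch used throughout the tests: a 300 x 300 um domain (61 x 61 grid)
# with the full-size physics, cheap enough for repeated stabilizations.
desk_params <- function(...) {
  ox_params(domain = c(-150, 150, -150, 150), ...)
}

# A tiny relaxed tissue with a handful of elements, deterministic.
desk_tissue <- function(comp = tissue_composition(3.5, 55, 30), seed = 1,
                        params = desk_params()) {
  relax_layout(sample_layout(comp, params, seed), params)
}

# Hand-built layout from explicit element positions.
manual_layout <- function(type, x, y, params = ox_params(), relaxed = FALSE) {
  r <- c(vessel = params$R_V, tumor = params$R_T, stromal = params$R_S)[type]
  df <- tibble::tibble(type = type, x_um = x, y_um = y, radius_um = unname(r))
  cyclox:::new_layout(df, tissue_composition(0, 0, 0), 0L, relaxed = relaxed)
}

# Independent steady-state oracle: Newton's method on the discretized
# reaction-diffusion equations (dense Jacobian; tiny grids only).
newton_steady <- function(masks, params, delta_V = 1, delta_T = 1,
                          tol = 1e-12, max_it = 200) {
  nr <- masks$dim[1]; nc <- masks$dim[2]; n <- nr * nc
  idx <- function(i, j) (j - 1) * nr + i
  # Laplacian with the conservative zero-flux stencil (absent neighbors drop)
  L <- matrix(0, n, n)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    k <- idx(i, j)
    nb <- list()
    if (i > 1) nb <- c(nb, idx(i - 1, j))
    if (i < nr) nb <- c(nb, idx(i + 1, j))
    if (j > 1) nb <- c(nb, idx(i, j - 1))
    if (j < nc) nb <- c(nb, idx(i, j + 1))
    for (q in nb) L[k, q] <- L[k, q] + 1
    L[k, k] <- L[k, k] - length(nb)
  }
  Dh <- params$D / params$dx^2
  src <- as.vector(delta_V * params$gamma_max * masks$vessel)
  upt <- as.vector(params$uptake_scale *
                     (delta_T * params$T_max * masks$tumor +
                        params$S_max * masks$stromal))
  g <- rep(0, n)
  for (it in seq_len(max_it)) {
    mm <- g / (params$kappa_m + g)
    f <- Dh * (L %*% g) + src - upt * mm
    if (max(abs(f)) < tol) break
    dmm <- params$kappa_m / (params$kappa_m + g)^2
    J <- Dh * L - diag(upt * dmm, n)
    g <- pmax(as.vector(g - solve(J, f)), 0)
  }
  matrix(g, nr, nc)
}

# Two-body relaxation oracle: overdamped Euler for a pair of equal disks,
# integrated directly from the update rule.
two_body_distance <- function(d0, R, params, iters = 10000) {
  d <- d0
  for (i in seq_len(iters)) {
    ov <- 2 * R - d
    if (ov <= 0) break
    step <- 2 * (params$dt_relax / params$nu) * params$stiffness * ov
    d <- d + step
    if (step / 2 < params$tol_disp) break
  }
  d
}
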