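test_that("indicator masks count nodes strictly inside the interaction radius", {
  p <- ox_params()
  # vessel centered exactly on a node: lattice points with i^2 + j^2 < 16
  lay <- manual_layout("vessel", 0, 0, p, relaxed = TRUE)
  m <- indicator_masks(lay, p)
  expect_equal(sum(m$vessel), 45L)
  expect_equal(sum(m$tumor), 0L)
  # any stromal cell covers at least one node (R_S > dx*sqrt(2)/2)
  set.seed(9)
  for (k in 1:25) {
    lay <- manual_layout("stromal", runif(1, -450, 450), runif(1, -450, 450), p)
    expect_gte(sum(indicator_masks(lay, p)$stromal), 1L)
  }
  # empty layout: all-zero masks
  empty <- manual_layout(character(0), numeric(0), numeric(0), p)
  m0 <- indicator_masks(empty, p)
  expect_equal(sum(m0$vessel) + sum(m0$tumor) + sum(m0$stromal), 0L)
})

test_that("single oxygen steps behave as hand computation dictates", {
  p <- desk_params()
  g <- cyclox:::grid_nodes(p)
  empty <- manual_layout(character(0), numeric(0), numeric(0), p)
  m0 <- indicator_masks(empty, p)
  zero <- cyclox:::new_field(matrix(0, g$nrow, g$ncol), p)
  # absorbing zero state without influx
  s1 <- step_oxygen(zero, m0, delta_V = 0, delta_T = 1, p)
  expect_true(all(s1$values == 0))
  # uniform field with no elements is unchanged (no-flux Laplacian of constant)
  uni <- cyclox:::new_field(matrix(42, g$nrow, g$ncol), p)
  s2 <- step_oxygen(uni, m0, 1, 1, p)
  expect_equal(s2$values, uni$values)
  # one vessel-covered node gains delta_V*gamma_max*dt in the first step
  one <- manual_layout("vessel", 0, 0, desk_params(R_V = 2), relaxed = TRUE)
  pm <- desk_params(R_V = 2) # covers only the node it sits on
  mv <- indicator_masks(one, pm)
  expect_equal(sum(mv$vessel), 1L)
  s3 <- step_oxygen(zero, mv, delta_V = 0.5, delta_T = 1, pm)
  expect_equal(max(s3$values), 0.5 * pm$gamma_max * pm$dt)
  expect_equal(sum(s3$values > 0), 1L)
})

test_that("rate bounds and the diffusion stability bound are enforced", {
  p <- desk_params()
  lay <- desk_tissue(params = p)
  m <- indicator_masks(lay, p)
  f <- cyclox:::new_field(matrix(0, 61, 61), p)
  expect_error(step_oxygen(f, m, delta_V = 1.2, 1, p), "delta_V")
  expect_error(step_oxygen(f, m, 1, delta_T = 51, p), "delta_T")
  expect_error(ox_params(dt = 0.2), "stability")
  expect_equal(ox_params()$D * ox_params()$dt / ox_params()$dx^2, 0.2)
})

test_that("average_po2 is the arithmetic node mean", {
  p <- desk_params()
  expect_equal(average_po2(cyclox:::new_field(matrix(60, 5, 5), p)), 60)
  expect_equal(average_po2(cyclox:::new_field(matrix(0, 5, 5), p)), 0)
  cb <- matrix(rep(c(0, 60), 18), 6, 6) # checkerboard on an even grid
  expect_equal(average_po2(cyclox:::new_field(cb, p)), 30)
})

test_that("stabilization matches the Newton steady-state oracle on a small grid", {
  # 11x11 grid, one vessel and one tumor cell; a narrow vessel and a large
  # uptake scale keep the saturable uptake able to balance the influx on
  # this tiny patch (a steady state must exist for either solver)
  p <- ox_params(domain = c(-25, 25, -25, 25), R_V = 6, uptake_scale = 800)
  lay <- manual_layout(c("vessel", "tumor"), c(-10, 12), c(-5, 8), p,
                       relaxed = TRUE)
  m <- indicator_masks(lay, p)
  st <- stabilize_oxygen(lay, p, masks = m)
  expect_true(st$report$converged)
  oracle <- newton_steady(m, p)
  expect_lt(max(abs(st$field$values - oracle)), 1e-6)
})

test_that("steady state balances total influx against total uptake", {
  p <- desk_params()
  lay <- desk_tissue(tissue_composition(3, 40, 30), seed = 4, params = p)
  m <- indicator_masks(lay, p)
  st <- stabilize_oxygen(lay, p, masks = m)
  g <- st$field$values
  influx <- sum(p$gamma_max * m$vessel)
  uptake <- sum(p$uptake_scale * (p$T_max * m$tumor + p$S_max * m$stromal) *
                  g / (p$kappa_m + g))
  expect_lt(abs(influx - uptake) / influx, 1e-6)
})

test_that("the stabilized level is independent of the initial concentration", {
  p <- desk_params()
  lay <- desk_tissue(tissue_composition(3.5, 55, 30), seed = 6, params = p)
  m <- indicator_masks(lay, p)
  avgs <- vapply(c(0, 30, 60), function(init)
    stabilize_oxygen(lay, p, init = init, masks = m)$report$average_po2,
    numeric(1))
  expect_lt(max(avgs) - min(avgs), 0.1)
})

test_that("steady-state average responds monotonically to the rates", {
  p <- desk_params()
  lay <- desk_tissue(tissue_composition(3, 40, 30), seed = 8, params = p)
  m <- indicator_masks(lay, p)
  by_dv <- vapply(c(0.25, 0.5, 1), function(dv)
    stabilize_oxygen(lay, p, delta_V = dv, masks = m)$report$average_po2,
    numeric(1))
  expect_true(all(diff(by_dv) > 0))
  by_dt <- vapply(c(0.5, 1, 2), function(dt)
    stabilize_oxygen(lay, p, delta_T = dt, masks = m)$report$average_po2,
    numeric(1))
  expect_true(all(diff(by_dt) < 0))
})

test_that("degenerate stabilizations are handled explicitly", {
  p <- desk_params()
  # no vessels, zero init: converges immediately to the zero field
  lay <- manual_layout(c("tumor", "stromal"), c(0, 30), c(0, 0), p,
                       relaxed = TRUE)
  st <- stabilize_oxygen(lay, p)
  expect_true(st$report$converged)
  expect_equal(st$report$average_po2, 0)
  expect_lte(st$report$iterations, 2L)
  # vessels without any cells cannot balance a constant influx
  ves <- manual_layout("vessel", 0, 0, p, relaxed = TRUE)
  expect_error(stabilize_oxygen(ves, p), "no cells")
})

test_that("schedule simulation preserves steady state and tracks the rates", {
  p <- desk_params()
  lay <- desk_tissue(tissue_composition(3, 40, 30), seed = 10, params = p)
  m <- indicator_masks(lay, p)
  st <- stabilize_oxygen(lay, p, masks = m)
  base <- st$report$average_po2
  # all-ones influx: the series stays at the stabilized average
  flat <- simulate_schedule(st$field, lay,
                            influx_schedule = new_schedule("influx", rep(1, 9), p),
                            params = p, masks = m)
  expect_equal(flat$t_min, c(4, 7, 10, 13, 16, 19, 22, 25, 28))
  expect_equal(flat$po2_mmHg, rep(base, 9), tolerance = 1e-4)
  # zero influx: strictly decreasing decay toward 0
  dead <- simulate_schedule(st$field, lay,
                            influx_schedule = new_schedule("influx", rep(0, 9), p),
                            params = p, masks = m)
  expect_true(all(diff(dead$po2_mmHg) < 0))
  expect_lt(dead$po2_mmHg[9], 0.05 * base)
  # doubling uptake in one segment lowers that segment's endpoint
  up <- rep(1, 9); up[4] <- 2
  bump <- simulate_schedule(st$field, lay,
                            uptake_schedule = new_schedule("uptake", up, p),
                            params = p, masks = m)
  expect_lt(bump$po2_mmHg[4], flat$po2_mmHg[4])
  expect_error(simulate_schedule(st$field, lay,
                                 influx_schedule = new_schedule("influx", rep(1, 9), p),
                                 uptake_schedule = new_schedule("uptake", rep(1, 9), p),
                                 params = p),
               "exactly one")
})
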