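test_that("composition_to_counts follows the nominal disk-area rule", {
  p <- ox_params()
  expect_equal(composition_to_counts(tissue_composition(3.5, 55, 30), p),
               c(N_V = 28L, N_T = 3112L, N_S = 6791L))
  expect_equal(composition_to_counts(tissue_composition(0, 0, 0), p),
               c(N_V = 0L, N_T = 0L, N_S = 0L))
  expect_equal(composition_to_counts(tissue_composition(0.5, 20, 75), p),
               c(N_V = 4L, N_T = 1132L, N_S = 16977L))
  expect_error(tissue_composition(50, 40, 20), "exceed")
  expect_error(tissue_composition(-1, 10, 10), "non-negative")
})

test_that("sample_layout is reproducible and respects the domain", {
  p <- ox_params()
  comp <- tissue_composition(2, 20, 10)
  a <- sample_layout(comp, p, seed = 7)
  b <- sample_layout(comp, p, seed = 7)
  c <- sample_layout(comp, p, seed = 8)
  expect_identical(a$x_um, b$x_um)
  expect_identical(a$y_um, b$y_um)
  expect_false(isTRUE(all.equal(a$x_um, c$x_um)))
  expect_true(all(a$x_um >= p$domain[1] & a$x_um <= p$domain[2]))
  expect_true(all(a$y_um >= p$domain[3] & a$y_um <= p$domain[4]))
  expect_equal(unname(table(a$type)[c("vessel", "tumor", "stromal")]),
               unname(composition_to_counts(comp, p)),
               ignore_attr = TRUE)
})

test_that("pairwise repulsion matches the Hookean contact law", {
  expect_equal(pairwise_repulsion(c(5, 0), c(-5, 0), 7.5, 7.5, 50), c(250, 0))
  # zero at and beyond contact
  expect_equal(pairwise_repulsion(c(15, 0), c(0, 0), 7.5, 7.5, 50), c(0, 0))
  expect_equal(pairwise_repulsion(c(100, 0), c(0, 0), 7.5, 7.5, 50), c(0, 0))
  # antisymmetry over random overlapping pairs
  set.seed(3)
  for (k in 1:20) {
    xi <- runif(2, -10, 10); xj <- xi + runif(2, -8, 8)
    if (sqrt(sum((xi - xj)^2)) < 1e-6) next
    f_ij <- pairwise_repulsion(xi, xj, 7.5, 3.75, 50)
    f_ji <- pairwise_repulsion(xj, xi, 3.75, 7.5, 50)
    expect_equal(f_ij, -f_ji)
  }
})

test_that("binned relaxation forces equal the all-pairs oracle", {
  p <- desk_params()
  lay <- sample_layout(tissue_composition(3, 30, 25), p, seed = 5)
  oracle <- cyclox:::pair_forces_cpp(lay$x_um, lay$y_um, lay$radius_um,
                                     lay$type != "vessel", p$stiffness)
  # one Euler step through the binned kernel reproduces oracle displacements
  res <- cyclox:::relax_cells_cpp(lay$x_um, lay$y_um, lay$radius_um,
                                  lay$type != "vessel",
                                  p$stiffness, p$nu, p$dt_relax, p$tol_disp,
                                  1L, p$domain[1], p$domain[2], p$domain[3],
                                  p$domain[4], p$overlap_tol, 0L, 0L, 1L)
  mv <- lay$type != "vessel"
  expected_x <- lay$x_um + (p$dt_relax / p$nu) * oracle[, 1]
  expected_y <- lay$y_um + (p$dt_relax / p$nu) * oracle[, 2]
  expected_x <- pmin(pmax(expected_x, p$domain[1]), p$domain[2])
  expected_y <- pmin(pmax(expected_y, p$domain[3]), p$domain[4])
  expect_equal(res$x[mv], expected_x[mv], tolerance = 1e-12)
  expect_equal(res$y[mv], expected_y[mv], tolerance = 1e-12)
  expect_equal(res$x[!mv], lay$x_um[!mv]) # vessels immobile
})

test_that("two overlapping cells separate to contact distance", {
  p <- ox_params()
  lay <- manual_layout(c("tumor", "tumor"), c(-5, 5), c(0, 0), p)
  rel <- relax_layout(lay, p)
  d <- sqrt(diff(rel$x_um)^2 + diff(rel$y_um)^2)
  # oracle: overdamped two-body integration of the same update rule
  d_oracle <- two_body_distance(10, p$R_T, p)
  expect_equal(d, d_oracle, tolerance = 1e-9)
  expect_gte(d, 2 * p$R_T - 0.02)
})

test_that("a layout with no overlaps is returned unchanged in one iteration", {
  p <- ox_params()
  lay <- manual_layout(c("tumor", "tumor", "stromal"),
                       c(-100, 100, 0), c(0, 0, 100), p)
  rel <- relax_layout(lay, p)
  expect_equal(attr(rel, "relaxation")$iterations, 1L)
  expect_equal(rel$x_um, lay$x_um)
  expect_equal(rel$y_um, lay$y_um)
  expect_false(attr(rel, "relaxation")$jammed)
})

test_that("relaxation resolves moderate densities and never moves vessels", {
  p <- ox_params()
  lay <- sample_layout(tissue_composition(2, 25, 20), p, seed = 13)
  rel <- relax_layout(lay, p)
  rep <- attr(rel, "relaxation")
  expect_true(rep$converged)
  expect_equal(rep$n_overlap, 0L)
  expect_equal(count_overlaps(rel, p), 0L) # independent O(n^2) recount
  ves <- lay$type == "vessel"
  expect_equal(rel$x_um[ves], lay$x_um[ves])
  expect_equal(rel$y_um[ves], lay$y_um[ves])
  # overlap count and energy decay monotonically along the trace
  tr <- rep$trace
  expect_true(all(diff(tr$n_overlap) <= 0))
  expect_true(all(diff(tr$overlap_energy) <= 1e-9))
  expect_true(all(rel$x_um >= p$domain[1] & rel$x_um <= p$domain[2]))
})

test_that("overfull packings come back flagged jammed, not as errors", {
  p <- desk_params()
  lay <- sample_layout(tissue_composition(4, 75, 20), p, seed = 2)
  rel <- relax_layout(lay, p)
  rep <- attr(rel, "relaxation")
  expect_true(rep$jammed)
  expect_gt(rep$n_overlap, 0)
  expect_true(isTRUE(attr(rel, "relaxed")))
})
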