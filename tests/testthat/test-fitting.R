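test_that("objective term and goodness of fit follow their definitions", {
  expect_equal(objective_term(30, 30), 0)
  expect_equal(objective_term(36.312, 36.315), 0.003)
  expect_equal(objective_term(2, 5), objective_term(5, 2))
  expect_equal(goodness_of_fit(c(10, 10), c(11, 9)), sqrt(2) / sqrt(200))
  expect_equal(goodness_of_fit(1:9, 1:9), 0)
  expect_equal(goodness_of_fit(c(5, 12, 3), c(0, 0, 0)), 1)
  # all-zero measured series: fall back to absolute RMS
  expect_equal(goodness_of_fit(c(0, 0), c(3, 4)), sqrt(12.5))
  # typeset alternative: per-point mean square
  expect_equal(goodness_of_fit(c(1, 2), c(2, 4), form = "mean_square"), 2.5)
  expect_error(goodness_of_fit(1:3, 1:4), "lengths")
})

test_that("schedules enforce their rate bounds", {
  p <- ox_params()
  expect_error(new_schedule("influx", rep(1.5, 9), p), "0, 1")
  expect_error(new_schedule("uptake", rep(-1, 9), p), "0, 50")
  expect_error(new_schedule("influx", rep(1, 8), p), "per segment")
  s <- new_schedule("uptake", c(1, 4.625, 50, 15.75, 50, 4.125, 50, 14.875, 9), p)
  expect_equal(s$boundaries, c(0, 4, 7, 10, 13, 16, 19, 22, 25, 28))
})

# One small stabilized tissue shared by the fitting tests.
fit_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      p <- desk_params()
      lay <- desk_tissue(tissue_composition(3, 40, 30), seed = 21, params = p)
      st <- stabilize_oxygen(lay, p)
      val <<- list(p = p, lay = lay, field = st$field,
                   base = st$report$average_po2)
    }
    val
  }
})

test_that("fit_segment recovers a known rate and respects bounds", {
  fx <- fit_fixture()
  # forward-simulate segment 1 at a known influx rate, then recover it
  m <- indicator_masks(fx$lay, fx$p)
  truth <- 0.62
  fwd <- cyclox:::run_segment(fx$field$values, m, 1, truth, 1, fx$p)
  fs <- fit_segment(fx$field, fx$lay, 1, fwd$average, "influx", fx$p,
                    search_options(), start_rate = 1, masks = m)
  so <- cyclox:::resolve_search(search_options(), "influx", fx$p)
  expect_lt(abs(fs$rate - truth), 4 * so$mesh_min + 1e-6)
  expect_lt(fs$error, so$fit_tol + 1e-6)
  expect_true(all(fs$trace$rate >= 0 & fs$trace$rate <= 1))
  # local-minimum certificate: no neighbor at mesh_min does better
  for (r in c(fs$rate - so$mesh_min, fs$rate + so$mesh_min)) {
    if (r < 0 || r > 1) next
    alt <- cyclox:::run_segment(fx$field$values, m, 1, r, 1, fx$p)
    expect_gte(abs(alt$average - fwd$average) + 1e-9, fs$error)
  }
  # a target already met by the starting rate returns immediately
  at_start <- cyclox:::run_segment(fx$field$values, m, 1, 1, 1, fx$p)
  fs1 <- fit_segment(fx$field, fx$lay, 1, at_start$average, "influx", fx$p,
                     search_options(), start_rate = 1, masks = m)
  expect_equal(fs1$rate, 1)
  expect_equal(fs1$evals, 1L)
})

test_that("segment endpoint responds monotonically to each rate", {
  fx <- fit_fixture()
  m <- indicator_masks(fx$lay, fx$p)
  ends_v <- vapply(c(0, 0.5, 1), function(r)
    cyclox:::run_segment(fx$field$values, m, 1, r, 1, fx$p)$average, numeric(1))
  expect_true(all(diff(ends_v) > 0))
  ends_t <- vapply(c(0.5, 1, 4), function(r)
    cyclox:::run_segment(fx$field$values, m, 1, 1, r, fx$p)$average, numeric(1))
  expect_true(all(diff(ends_t) < 0))
})

test_that("a flat series at the stabilized level fits with all-ones influx", {
  fx <- fit_fixture()
  flat <- make_roi_series(fx$base, "flat")
  fit <- fit_schedule(fx$field, fx$lay, flat, "influx", fx$p)
  expect_equal(fit$schedule$rates, rep(1, 9))
  expect_lt(fit$gof, 1e-3)
  expect_s3_class(fit, "schedule_fit")
  td <- tidy(fit)
  expect_equal(nrow(td), 9L)
  expect_equal(td$rate, fit$schedule$rates)
  gl <- glance(fit)
  expect_equal(gl$kind, "influx")
  expect_equal(gl$gof, fit$gof)
})

test_that("fitting a forward-simulated influx schedule recovers its series", {
  fx <- fit_fixture()
  set.seed(77)
  truth <- new_schedule("influx", round(runif(9, 0.2, 1), 3), fx$p)
  fwd <- forward_series(fx$lay, fx$field, truth, fx$p)
  fit <- fit_schedule(fx$field, fx$lay, fwd$series, "influx", fx$p)
  expect_lt(fit$gof, 0.02) # recovery closure at desk scale
  expect_true(all(fit$schedule$rates >= 0 & fit$schedule$rates <= 1))
  # refitting the fitted series changes the fit only marginally
  refit <- fit_schedule(fx$field, fx$lay, fit$simulated, "influx", fx$p)
  expect_lt(abs(refit$gof), 1e-3 + fit$gof)
})
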