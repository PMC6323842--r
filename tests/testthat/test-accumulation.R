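# shared plan for the accumulation tests
acc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- small_grid()
      itv <- build_itv(grid, 2, -5:5)
      cache <<- list(
        grid = grid,
        gtv = make_gtv_mask(grid, target_geometry(2, 0)),
        dose = plan_dose(itv, plan_spec())
      )
    }
    cache
  }
})

test_that("displacement sampling is the identity at z = 0 and clamps out of range", {
  fx <- acc_fixture()
  d0 <- sample_dose_at_displacement(fx$dose, fx$gtv, 0)
  expect_identical(d0, fx$dose$dose[fx$gtv$mask])
  expect_warning(d16 <- sample_dose_at_displacement(fx$dose, fx$gtv, 16.2),
                 "clamped")
  expect_identical(d16, sample_dose_at_displacement(fx$dose, fx$gtv, 15))
})

test_that("a spatially uniform dose is invariant under any displacement", {
  fx <- acc_fixture()
  uni <- fx$dose
  uni$dose <- array(42, dim(uni$dose))
  for (z in c(-15, -3.6, 0, 7, 15)) {
    expect_equal(sample_dose_at_displacement(uni, fx$gtv, z, round_mm = FALSE),
                 rep(42, sum(fx$gtv$mask)))
  }
})

test_that("a linear SI dose ramp shifts by slope times displacement", {
  fx <- acc_fixture()
  ramp <- fx$dose
  g <- 0.5 # Gy per mm along SI
  si_mm <- dose4d:::grid_axes_mm(fx$grid)[[3]]
  ramp$dose <- array(rep(100 + g * si_mm, each = prod(fx$grid$shape[1:2])),
                     dim = fx$grid$shape)
  base <- sample_dose_at_displacement(ramp, fx$gtv, 0)
  for (z in c(3, -4, 2.25)) {
    shifted <- sample_dose_at_displacement(ramp, fx$gtv, z, round_mm = FALSE)
    expect_equal(shifted, base + g * z, tolerance = 1e-9)
  }
})

test_that("accumulation equals an independent brute-force loop within 1e-12", {
  fx <- acc_fixture()
  set.seed(77)
  z <- runif(7, -12, 12)
  acc <- suppressWarnings(accumulate(fx$dose, fx$gtv, z))
  # oracle: plain loop over per-displacement samples
  oracle <- rep(0, sum(fx$gtv$mask))
  for (zi in z) {
    oracle <- oracle + sample_dose_at_displacement(fx$dose, fx$gtv, zi)
  }
  oracle <- oracle / length(z)
  expect_equal(acc$dose_gy, oracle, tolerance = 1e-12)
  expect_identical(acc$sample_count, 7L)
  # two-displacement mean and the all-zero identity
  d1 <- sample_dose_at_displacement(fx$dose, fx$gtv, 2)
  d2 <- sample_dose_at_displacement(fx$dose, fx$gtv, -5)
  acc2 <- accumulate(fx$dose, fx$gtv, c(2, -5))
  expect_equal(acc2$dose_gy, (d1 + d2) / 2, tolerance = 1e-12)
  acc0 <- accumulate(fx$dose, fx$gtv, c(0, 0, 0))
  expect_equal(acc0$dose_gy, fx$dose$dose[fx$gtv$mask])
  expect_error(accumulate(fx$dose, fx$gtv, numeric(0)), "non-empty")
})

test_that("accumulation is linear over concatenated displacement lists", {
  fx <- acc_fixture()
  set.seed(8)
  l1 <- runif(4, -10, 10)
  l2 <- runif(9, -10, 10)
  a1 <- accumulate(fx$dose, fx$gtv, l1)$dose_gy
  a2 <- accumulate(fx$dose, fx$gtv, l2)$dose_gy
  both <- accumulate(fx$dose, fx$gtv, c(l1, l2))$dose_gy
  expect_equal(both, (4 * a1 + 9 * a2) / 13, tolerance = 1e-12)
})

test_that("the traditional accumulation records I = 10 and reproduces the static null", {
  fx <- acc_fixture()
  tr <- homogeneous_trace(A = 8, P = 4)
  ph <- phase_sample_cycles(tr)
  acc <- accumulate_4d_traditional(fx$dose, fx$gtv, ph[1, ])
  expect_identical(acc$sample_count, 10L)
  expect_identical(acc$label, "D4D")
  expect_error(accumulate_4d_traditional(fx$dose, fx$gtv, ph[1, 1:9]),
               "exactly 10")
  # zero-amplitude curve: equals the static dose
  null <- accumulate_4d_traditional(fx$dose, fx$gtv, rep(0, 10))
  expect_equal(null$dose_gy, fx$dose$dose[fx$gtv$mask])
})

test_that("the true accumulation resamples 100 s at 0.4 s into 250 samples", {
  fx <- acc_fixture()
  tr <- homogeneous_trace(A = 8, P = 4)
  acc <- accumulate_true(fx$dose, fx$gtv, tr)
  expect_identical(acc$sample_count, 250L)
  flat <- dose4d:::new_breathing_trace(seq(0, 100, 0.02),
                                       rep(0, 5001), 0.02)
  expect_equal(accumulate_true(fx$dose, fx$gtv, flat)$dose_gy,
               fx$dose$dose[fx$gtv$mask])
})

test_that("Dx matches a sort-based oracle exactly on small random instances", {
  # worked examples: five voxels, prescription 60
  v <- c(70, 65, 60, 55, 50)
  expect_equal(dose_at_volume(v, 60, 60), 100)        # rank ceil(3) -> 60 Gy
  expect_equal(dose_at_volume(v, 100, 60), 100 * 50 / 60) # the minimum, 83.33%
  expect_equal(dose_at_volume(rep(60, 9), 99, 60), 100)
  set.seed(99)
  for (i in 1:25) {
    n <- sample(1:100, 1)
    doses <- runif(n, 0, 80)
    x <- runif(1, 1, 100)
    sorted <- sort(doses, decreasing = TRUE)
    oracle <- 100 * sorted[ceiling(x / 100 * n)] / 60
    expect_identical(dose_at_volume(doses, x, 60), oracle)
  }
  expect_error(dose_at_volume(numeric(0), 99, 60), "empty")
  expect_error(dose_at_volume(v, 0, 60), "x_percent")
})

test_that("Dx is monotone in x and bounded by the constituent single-shift Dx", {
  fx <- acc_fixture()
  set.seed(5)
  z <- sample(-10:10, 6)
  acc <- accumulate(fx$dose, fx$gtv, z)
  xs <- c(5, 25, 50, 75, 90, 95, 99, 100)
  dx <- vapply(xs, function(x) dose_at_volume(acc, x), numeric(1))
  expect_true(all(diff(dx) <= 1e-12))
  for (x in c(95, 99)) {
    singles <- vapply(z, function(zi) {
      dose_at_volume(sample_dose_at_displacement(fx$dose, fx$gtv, zi), x, 60)
    }, numeric(1))
    d <- dose_at_volume(acc, x)
    expect_gte(d, min(singles) - 1e-9)
    expect_lte(d, max(singles) + 1e-9)
  }
})

test_that("the DVH curve starts at full volume and never increases", {
  fx <- acc_fixture()
  acc <- accumulate(fx$dose, fx$gtv, c(-4, 0, 4))
  dvh <- dvh_curve(acc)
  expect_equal(dvh$volume_fraction[1], 1)
  expect_true(all(diff(dvh$volume_fraction) <= 0))
})
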