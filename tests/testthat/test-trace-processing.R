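test_that("the low-pass filter is zero-phase, passes DC and the breathing band", {
  n <- 3001
  t <- seq(0, 100, length.out = n)
  dt <- t[2] - t[1]
  const <- dose4d:::new_breathing_trace(t, rep(2.5, n), dt)
  expect_equal(lowpass_filter(const, 1)$displacement_mm, rep(2.5, n),
               tolerance = 1e-9)

  sin025 <- dose4d:::new_breathing_trace(t, sin(2 * pi * 0.25 * t), dt)
  f <- lowpass_filter(sin025, 1)
  core <- 300:2700 # avoid the filtfilt edge transients
  fit <- lm(f$displacement_mm[core] ~ sin(2 * pi * 0.25 * t[core]) +
              cos(2 * pi * 0.25 * t[core]) - 1)
  amp <- sqrt(sum(coef(fit)^2))
  expect_lt(abs(amp - 1), 0.02) # amplitude preserved within 2%
  # no time shift: peak positions unchanged
  expect_lt(max(abs(f$displacement_mm[core] - sin025$displacement_mm[core])),
            0.02)

  mixed <- dose4d:::new_breathing_trace(
    t, sin(2 * pi * 0.25 * t) + sin(2 * pi * 10 * t), dt
  )
  g <- lowpass_filter(mixed, 1)
  resid <- g$displacement_mm[core] - f$displacement_mm[core]
  fit10 <- lm(resid ~ sin(2 * pi * 10 * t[core]) + cos(2 * pi * 10 * t[core]) - 1)
  amp10 <- sqrt(sum(coef(fit10)^2))
  expect_lt(20 * log10(1 / max(amp10, 1e-12)), Inf)
  expect_gt(-20 * log10(amp10), 20) # >= 20 dB attenuation at 10 Hz

  expect_error(lowpass_filter(sin025, cutoff_hz = 20), "Nyquist")
})

test_that("segmentation of a homogeneous trace finds the analytic cycle count", {
  tr <- homogeneous_trace(A = 10, P = 4)
  seg <- segment_cycles(tr)
  expect_equal(nrow(seg$full_cycles), 25) # 100 s / 4 s
  expect_true(abs(nrow(seg$segments) - 50) <= 1)
  # peaks and valleys alternate
  expect_true(all(abs(diff(seg$extrema$type)) == 2))
  expect_error(segment_cycles(dose4d:::new_breathing_trace(0:10 / 10,
                                                           rep(0, 11), 0.1)),
               "no extremum")
})

test_that("filtering then segmenting a noisy trace recovers the generator cycle count", {
  for (seed in c(11L, 12L, 13L)) {
    prm <- motion_params(15.28, 0.23, 2.71, 0.08, seed = seed)
    noisy <- generate_patient_like_trace(patient_like_params(prm, noise_sd_mm = 0.5))
    filt <- lowpass_filter(noisy, 1)
    seg <- segment_cycles(filt)
    truth <- sum(noisy$cycles$complete)
    expect_lte(abs(nrow(seg$full_cycles) - truth), 1)
  }
})

test_that("phase sampling takes the ten interval-midpoint displacements", {
  tr <- homogeneous_trace(A = 10, P = 4)
  # peak-to-valley half cycle [0, 2] s: midpoints 0.1, 0.3, ..., 1.9
  ps <- phase_sample_segment(tr, c(1, which(tr$time_s == 2)))
  expect_equal(ps, cos4_displacement(10, 4, seq(0.1, 1.9, by = 0.2)),
               tolerance = 1e-6)
  expect_equal(round(ps[1], 3), 4.877)
  expect_equal(round(ps[10], 3), -5)
  # monotone segment gives strictly decreasing phase samples
  expect_true(all(diff(ps) < 0))
  expect_error(phase_sample_segment(tr, c(5, 5)), "degenerate")
})

test_that("homogeneous traces give identical phase sets for every cycle", {
  tr <- homogeneous_trace(A = 10, P = 4)
  ph <- phase_sample_cycles(tr, mode = "full_cycle")
  expect_equal(ncol(ph), 10)
  expect_lt(max(apply(ph, 2, function(col) diff(range(col)))), 1e-6)
  # half-cycle mode alternates descending and ascending segments; each
  # parity class is internally identical
  ph2 <- phase_sample_cycles(tr, mode = "half_cycle")
  for (par in c(1, 0)) {
    sel <- ph2[seq_len(nrow(ph2)) %% 2 == par, , drop = FALSE]
    expect_lt(max(apply(sel, 2, function(col) diff(range(col)))), 1e-6)
  }
})

test_that("the occupancy pdf matches a quadrature oracle and conserves mass", {
  tr <- homogeneous_trace(A = 10, P = 4)
  pdf <- empirical_position_pdf(tr)
  expect_equal(sum(pdf$probabilities), 1, tolerance = 1e-9)
  # oracle: time fraction per 1-mm bin from dense evaluation of one cycle
  tt <- seq(0, 4, length.out = 400001)[-400001]
  zz <- round_half_away(cos4_displacement(10, 4, tt))
  oracle <- table(zz) / length(zz)
  for (b in names(oracle)) {
    p_impl <- pdf$probabilities[pdf$positions_mm == as.numeric(b)]
    expect_lt(abs(p_impl - as.numeric(oracle[b])), 0.01)
  }
  # the cos^4 waveform dwells far longer near the valley than the peak
  expect_gt(pdf$probabilities[pdf$positions_mm == -5],
            2 * pdf$probabilities[pdf$positions_mm == 5])
})

test_that("degenerate traces give the expected point-mass pdfs", {
  t <- seq(0, 10, by = 0.1)
  const <- dose4d:::new_breathing_trace(t, rep(0, length(t)), 0.1)
  p1 <- empirical_position_pdf(const)
  expect_identical(p1$positions_mm, 0)
  expect_identical(p1$probabilities, 1)
  alt <- dose4d:::new_breathing_trace(t, rep(c(-3, 3), length.out = length(t)), 0.1)
  p2 <- empirical_position_pdf(alt)
  expect_equal(p2$positions_mm, c(-3, 3))
  expect_equal(p2$probabilities, c(0.5, 0.5), tolerance = 0.01)
})

test_that("coverage_interval walks the cumulative distribution with equal tails", {
  point <- dose4d:::new_position_pdf(0, 1)
  expect_equal(unname(coverage_interval(point, 0.8)), c(0, 0))
  tri <- dose4d:::new_position_pdf(c(-1, 0, 1), c(0.25, 0.5, 0.25))
  expect_equal(unname(coverage_interval(tri, 0.8)), c(-1, 1))
  # brute-force cumulative-walk oracle on random pdfs, and monotonicity
  set.seed(123)
  for (i in 1:20) {
    pos <- sort(sample(-10:10, 7))
    pr <- runif(7); pr <- pr / sum(pr)
    pdf <- dose4d:::new_position_pdf(pos, pr)
    for (cov in c(0.5, 0.8, 0.95)) {
      ci <- coverage_interval(pdf, cov)
      cum <- cumsum(pdf$probabilities)
      tail <- (1 - cov) / 2
      lo_o <- pdf$positions_mm[which(cum >= tail - 1e-12)[1]]
      hi_o <- pdf$positions_mm[which(cum >= 1 - tail - 1e-12)[1]]
      expect_identical(unname(ci), c(lo_o, hi_o))
    }
    wide <- coverage_interval(pdf, 0.95)
    narrow <- coverage_interval(pdf, 0.5)
    expect_lte(wide["lo"], narrow["lo"])
    expect_gte(wide["hi"], narrow["hi"])
  }
  expect_error(coverage_interval(tri, 0), "coverage")
  expect_error(coverage_interval(tri, 1.2), "coverage")
})

test_that("the cycle-extreme pdf reflects per-cycle peak and valley positions", {
  tr <- homogeneous_trace(A = 10, P = 4)
  pdf <- cycle_extreme_pdf(tr)
  expect_setequal(pdf$positions_mm, c(-5, 5))
  expect_equal(pdf$probabilities, c(0.5, 0.5), tolerance = 0.05)
})
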