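test_that("motion_params validates its invariants", {
  expect_s3_class(motion_params(10, 0.25, 4, 0.2), "motion_params")
  expect_error(motion_params(-1), "mean_amplitude_mm")
  expect_error(motion_params(10, -0.1), "amplitude_cv")
  expect_error(motion_params(10, 0.2, 0), "mean_period_s")
  expect_error(motion_params(10, 0.2, 4, 0.1, duration_s = 0), "duration_s")
})

test_that("zero-variance cycle draws return the means exactly", {
  p <- motion_params(10, 0, 4, 0, seed = 7)
  set.seed(42)
  cp <- sample_cycle_params(p, 5)
  expect_identical(cp$amplitude_mm, rep(10, 5))
  expect_identical(cp$period_s, rep(4, 5))
})

test_that("cycle amplitude draws recover the Gaussian within 3 standard errors", {
  p <- motion_params(15, 0.25, 4, 0.2, seed = 1)
  set.seed(20190108)
  cp <- sample_cycle_params(p, 10000)
  n <- nrow(cp)
  se_mean <- 3.75 / sqrt(n)
  se_sd <- 3.75 / sqrt(2 * (n - 1))
  expect_lt(abs(mean(cp$amplitude_mm) - 15), 3 * se_mean + 0.01 * 15)
  expect_lt(abs(sd(cp$amplitude_mm) - 3.75), 3 * se_sd + 0.05)
  # redraw truncation leaves no draws at or below the floor
  expect_true(all(cp$amplitude_mm > 0.5))
  expect_true(all(cp$period_s > 0.5))
})

test_that("the cos^4 waveform takes its documented values", {
  tr <- homogeneous_trace()
  # peak at t = 0, valley at t = P/2, peak-to-peak = A
  expect_equal(tr$displacement_mm[1], 5)
  expect_equal(tr$displacement_mm[tr$time_s == 2], -5)
  expect_equal(max(tr$displacement_mm) - min(tr$displacement_mm), 10)
  # direct evaluation between the extremes
  expect_equal(tr$displacement_mm[tr$time_s == 0.1],
               10 * (cos(pi * 0.1 / 4)^4 - 0.5))
  expect_equal(round(tr$displacement_mm[tr$time_s == 0.1], 3), 4.877)
})

test_that("traces are deterministic in the seed and bounded by the cycle amplitudes", {
  p <- motion_params(15, 0.25, 4, 0.2, seed = 99)
  t1 <- simulate_trace(p)
  t2 <- simulate_trace(p)
  expect_identical(t1, t2)
  # every sample lies within +-A/2 of its own cycle
  k <- findInterval(t1$time_s, t1$cycles$start_s)
  expect_true(all(abs(t1$displacement_mm) <=
                    t1$cycles$amplitude_mm[k] / 2 + 1e-9))
})

test_that("cycle junctions jump by at most half the amplitude difference", {
  p <- motion_params(15, 0.35, 4, 0.3, seed = 5)
  tr <- simulate_trace(p)
  cyc <- tr$cycles
  for (j in seq_len(nrow(cyc) - 1)) {
    t_j <- cyc$start_s[j + 1]
    i <- findInterval(t_j, tr$time_s)
    jump <- abs(tr$displacement_mm[min(i + 1, length(tr$time_s))] -
                  tr$displacement_mm[i])
    bound <- abs(cyc$amplitude_mm[j] - cyc$amplitude_mm[j + 1]) / 2
    expect_lte(jump, bound + 0.05) # slack for the finite sample step
  }
})

test_that("the scenario bank enumerates rows x replicates with derived seeds", {
  sc <- table1_scenarios()
  bank <- generate_scenario_bank(sc[1, , drop = FALSE], replicates = 1,
                                 base_seed = 11L)
  expect_length(bank, 1)
  expect_gte(max(bank[[1]]$time_s), 100)
  bank3 <- generate_scenario_bank(sc[1:3, ], replicates = 2, base_seed = 11L)
  expect_length(bank3, 6)
  m <- attr(bank3, "manifest")
  expect_identical(m$seed, as.integer(11 + 1000 * m$row + m$replicate))
  # identical base seed reproduces the bank byte for byte
  bank3b <- generate_scenario_bank(sc[1:3, ], replicates = 2, base_seed = 11L)
  expect_identical(lapply(bank3, unclass), lapply(bank3b, unclass))
})

test_that("malformed scenario rows are rejected with the field named", {
  sc <- table1_scenarios()[1:2, ]
  expect_error(generate_scenario_bank(sc[, -2], replicates = 1),
               "mean_excursion_mm")
  sc$period_cv[2] <- -1
  expect_error(generate_scenario_bank(sc, replicates = 1), "period_cv")
})

test_that("patient-like traces resample the same cycles at 30 Hz", {
  prm <- motion_params(15.28, 0.23, 2.71, 0.08, seed = 3)
  clean <- generate_patient_like_trace(patient_like_params(prm, noise_sd_mm = 0))
  expect_length(clean$time_s, 3001) # 100 s at 30 Hz
  # with zero noise the samples equal the model evaluated at 30 Hz
  base <- simulate_trace(prm)
  k <- findInterval(clean$time_s, base$cycles$start_s)
  expect_equal(clean$displacement_mm,
               cos4_displacement(base$cycles$amplitude_mm[k],
                                 base$cycles$period_s[k],
                                 clean$time_s - base$cycles$start_s[k]))
  noisy <- generate_patient_like_trace(patient_like_params(prm, noise_sd_mm = 0.5))
  expect_false(identical(noisy$displacement_mm, clean$displacement_mm))
  expect_lt(abs(sd(noisy$displacement_mm - clean$displacement_mm) - 0.5), 0.05)
})

test_that("trace CSV round trip is lossless", {
  tr <- simulate_trace(motion_params(12, 0.2, 4, 0.1, duration_s = 10, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_identical(back$time_s, tr$time_s)
  expect_identical(back$displacement_mm, tr$displacement_mm)
  unlink(path)
})
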