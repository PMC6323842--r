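#' Simulation scenario grid
#'
#' The ten breathing-pattern combinations of the simulation study: a mean
#' amplitude sweep 5-20 mm, an amplitude-cv sweep 0.15-0.35, a mean period
#' sweep 3-5 s and a period-cv sweep 0.1-0.3, each varied about the base
#' pattern (15 mm, cv 0.25, 4 s, cv 0.2). Each row is simulated 10 times in
#' the full study, giving 100 breathing curves.
#'
#' @return data.frame with columns `no`, `mean_excursion_mm`, `excursion_cv`,
#'   `mean_period_s`, `period_cv`.
#' @export
table1_scenarios <- function() {
  data.frame(
    no = 1:10,
    mean_excursion_mm = c(5, 10, 15, 20, 15, 15, 15, 15, 15, 15),
    excursion_cv      = c(0.25, 0.25, 0.25, 0.25, 0.15, 0.35, 0.25, 0.25, 0.25, 0.25),
    mean_period_s     = c(4, 4, 4, 4, 4, 4, 3, 5, 4, 4),
    period_cv         = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.1, 0.3)
  )
}

#' Measured per-fraction respiratory characteristics of three patients
#'
#' Per-fraction mean excursion, excursion cv, mean period and period cv of
#' the superior-inferior fiducial motion of three early-stage lung-cancer
#' patients tracked at 30 Hz over five treatment fractions each. These rows
#' parameterize the synthetic patient-like trace generator.
#'
#' @return data.frame with columns `patient`, `fraction`,
#'   `mean_excursion_mm`, `excursion_cv`, `mean_period_s`, `period_cv`.
#' @export
table3_patients <- function() {
  data.frame(
    patient = rep(1:3, each = 5),
    fraction = rep(1:5, times = 3),
    mean_excursion_mm = c(
      10.11, 10.32, 10.14, 9.88, 8.59,
      10.21, 9.92, 10.53, 10.62, 10.05,
      15.28, 14.36, 16.21, 15.88, 15.20
    ),
    excursion_cv = c(
      0.12, 0.09, 0.12, 0.11, 0.09,
      0.23, 0.20, 0.23, 0.25, 0.22,
      0.23, 0.20, 0.21, 0.23, 0.22
    ),
    mean_period_s = c(
      4.85, 4.65, 4.95, 5.15, 5.05,
      3.78, 3.81, 3.85, 3.39, 3.78,
      2.71, 2.79, 3.18, 3.11, 3.06
    ),
    period_cv = c(
      0.12, 0.09, 0.08, 0.09, 0.12,
      0.05, 0.09, 0.09, 0.15, 0.05,
      0.08, 0.08, 0.11, 0.10, 0.10
    )
  )
}
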