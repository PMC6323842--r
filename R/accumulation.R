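#' Dose to the reference GTV voxels under a rigid SI shift
#'
#' Looks up the planned dose at every reference-GTV voxel displaced rigidly
#' by `z_mm` along the SI axis (the deforming of each phase dose back to the
#' reference image, which is exact for rigid motion of this phantom).
#' Displacements beyond the phantom's sample range are clamped with a
#' warning. With `round_mm = TRUE` (the default, matching the 1-mm
#' sample-image bank) the displacement is first rounded to integer mm; with
#' rounding off, dose is linearly interpolated along SI.
#'
#' @param dose a `dose_field` from [plan_dose()].
#' @param gtv_ref the reference (SI = 0) GTV `volume_mask`.
#' @param z_mm scalar SI displacement (mm, positive superior).
#' @param round_mm round the displacement to integer mm before lookup.
#' @param clamp_range_mm clamp |z| to this range (default 15).
#' @return numeric vector of per-voxel doses (Gy) over the GTV voxels.
#' @export
sample_dose_at_displacement <- function(dose, gtv_ref, z_mm,
                                        round_mm = TRUE,
                                        clamp_range_mm = 15) {
  stopifnot(inherits(dose, "dose_field"), inherits(gtv_ref, "volume_mask"))
  stop_if_not_scalar_number(z_mm, "z_mm")
  if (abs(z_mm) > clamp_range_mm) {
    warning(sprintf("displacement %.2f mm clamped to +-%g mm", z_mm,
                    clamp_range_mm))
    z_mm <- sign(z_mm) * clamp_range_mm
  }
  if (round_mm) z_mm <- round_half_away(z_mm)
  shift_dose_vector(dose, gtv_ref, z_mm)
}

# internal: dose at GTV voxels shifted z_mm along SI, linear interp between
# integer voxel planes; no clamping/rounding here
shift_dose_vector <- function(dose, gtv_ref, z_mm) {
  grid <- dose$grid
  kf <- z_mm / grid$voxel_mm
  k0 <- floor(kf)
  frac <- kf - k0
  cache <- gtv_index_cache(gtv_ref)
  d0 <- dose$dose[shifted_indices(cache, grid, k0)]
  if (frac == 0) return(d0)
  d1 <- dose$dose[shifted_indices(cache, grid, k0 + 1)]
  (1 - frac) * d0 + frac * d1
}

# linear indices of the GTV voxels plus their SI voxel index, memoized on
# the mask object
gtv_index_cache <- function(gtv_ref) {
  cache <- attr(gtv_ref, "index_cache")
  if (!is.null(cache)) return(cache)
  grid <- gtv_ref$grid
  lin <- which(gtv_ref$mask)
  stride <- prod(grid$shape[seq_len(grid$si_axis - 1)])
  si_idx <- ((lin - 1) %/% stride) %% grid$shape[grid$si_axis] + 1
  list(lin = lin, stride = stride, si_idx = si_idx)
}

shifted_indices <- function(cache, grid, k) {
  si <- cache$si_idx + k
  if (any(si < 1) || any(si > grid$shape[grid$si_axis])) {
    stop("shifted target leaves the phantom grid; enlarge the grid")
  }
  cache$lin + k * cache$stride
}

#' Dose lookup matrix over integer SI shifts
#'
#' Precomputes the per-voxel dose of the reference GTV under every integer
#' displacement in `z_range_mm`; column `j` is the dose vector for shift
#' `z_range_mm[j]`. Accumulation over a long displacement list then reduces
#' to a weighted column average.
#'
#' @inheritParams sample_dose_at_displacement
#' @param z_range_mm integer displacements to tabulate.
#' @return numeric matrix, one row per GTV voxel, one column per shift
#'   (named by displacement).
#' @export
dose_shift_matrix <- function(dose, gtv_ref, z_range_mm = -15:15) {
  cols <- vapply(z_range_mm, function(z) shift_dose_vector(dose, gtv_ref, z),
                 numeric(sum(gtv_ref$mask)))
  colnames(cols) <- as.character(z_range_mm)
  cols
}

new_accumulated_dose <- function(dose_gy, displacements_mm, prescription_gy,
                                 label = "accumulated") {
  structure(
    list(dose_gy = dose_gy, sample_count = length(displacements_mm),
         displacements_mm = displacements_mm,
         prescription_gy = prescription_gy, label = label),
    class = "accumulated_dose"
  )
}

#' @export
print.accumulated_dose <- function(x, ...) {
  cat(sprintf("%s dose over %d voxels, I = %d samples, mean %.2f Gy\n",
              x$label, length(x$dose_gy), x$sample_count, mean(x$dose_gy)))
  invisible(x)
}

#' Accumulate dose over a displacement list
#'
#' Per-voxel arithmetic mean of the shifted doses:
#' \deqn{D(e) = \frac{1}{I} \sum_{i=1}^I d(x_i(e))}
#' over the `I` displacement samples.
#'
#' @inheritParams sample_dose_at_displacement
#' @param displacements_mm non-empty numeric vector of SI displacements (mm).
#' @param label provenance label for the result.
#' @return an `accumulated_dose` (per-voxel mean dose over the reference
#'   GTV, sample count `I`, and the displacements used after
#'   rounding/clamping).
#' @export
accumulate <- function(dose, gtv_ref, displacements_mm, round_mm = TRUE,
                       clamp_range_mm = 15, label = "accumulated") {
  if (length(displacements_mm) == 0) {
    stop("'displacements_mm' must be non-empty")
  }
  z <- displacements_mm
  n_clamped <- sum(abs(z) > clamp_range_mm)
  if (n_clamped > 0) {
    warning(sprintf("%d displacement(s) clamped to +-%g mm", n_clamped,
                    clamp_range_mm))
    z <- pmin(pmax(z, -clamp_range_mm), clamp_range_mm)
  }
  if (round_mm) {
    z <- round_half_away(z)
    tb <- table(z)
    zu <- as.numeric(names(tb))
    w <- as.numeric(tb) / length(z)
    acc <- 0
    for (j in seq_along(zu)) {
      acc <- acc + w[j] * shift_dose_vector(dose, gtv_ref, zu[j])
    }
  } else {
    acc <- 0
    for (zi in z) acc <- acc + shift_dose_vector(dose, gtv_ref, zi)
    acc <- acc / length(z)
  }
  new_accumulated_dose(acc, z, dose$spec$prescription_gy, label)
}

#' Traditional ten-phase accumulated dose (one cycle)
#'
#' Accumulates over the 10 phase-sampled displacements of a single breathing
#' cycle (`I = 10`), the per-cycle 4DCT-based accumulated dose.
#'
#' @inheritParams accumulate
#' @param phase_samples_mm the 10 phase displacements of one cycle, e.g. a
#'   row of [phase_sample_cycles()].
#' @return an `accumulated_dose` labelled `"D4D"`.
#' @export
accumulate_4d_traditional <- function(dose, gtv_ref, phase_samples_mm,
                                      round_mm = TRUE, clamp_range_mm = 15) {
  if (length(phase_samples_mm) != 10) {
    stop("a traditional phase set has exactly 10 displacements")
  }
  accumulate(dose, gtv_ref, phase_samples_mm, round_mm = round_mm,
             clamp_range_mm = clamp_range_mm, label = "D4D")
}

#' True accumulated dose over the whole breathing trace
#'
#' Resamples the trace uniformly at `sample_interval_s` (0.4 s by default,
#' giving ~250 samples over a 100-s session), rounds the displacements to
#' the phantom's integer-mm bank and accumulates over all of them. Samples
#' are taken at the midpoints of the resampling intervals, the same
#' midpoint rule the ten-phase sorting uses, so homogeneous breathing gives
#' matching traditional and true accumulations up to the residual of
#' incommensurate periods.
#'
#' @inheritParams accumulate
#' @param trace a `breathing_trace`.
#' @param sample_interval_s time step of the uniform resampling (s).
#' @return an `accumulated_dose` labelled `"Dtrue"`.
#' @export
accumulate_true <- function(dose, gtv_ref, trace, sample_interval_s = 0.4,
                            round_mm = TRUE, clamp_range_mm = 15) {
  stopifnot(inherits(trace, "breathing_trace"))
  duration <- max(trace$time_s)
  if (duration < sample_interval_s) {
    stop("trace must be at least one sampling interval long")
  }
  n <- floor(duration / sample_interval_s)
  times <- (seq_len(n) - 0.5) * sample_interval_s
  z <- approx(trace$time_s, trace$displacement_mm, xout = times)$y
  acc <- accumulate(dose, gtv_ref, z, round_mm = round_mm,
                    clamp_range_mm = clamp_range_mm, label = "Dtrue")
  acc
}

#' Dose covering x% of the target (Dx)
#'
#' The largest dose level received by at least `x`% of the target volume:
#' voxel doses are sorted in decreasing order and `D_x` is the dose at rank
#' `ceil(x/100 * N)` (no interpolation; the conservative lower value),
#' returned as a percentage of the prescription.
#'
#' @param acc an `accumulated_dose` (or numeric vector of voxel doses).
#' @param x_percent volume percentage in (0, 100].
#' @param prescription_gy prescription dose; defaults to the one recorded in
#'   `acc`.
#' @return `D_x` as a percentage of the prescription.
#' @export
dose_at_volume <- function(acc, x_percent, prescription_gy = NULL) {
  doses <- if (inherits(acc, "accumulated_dose")) acc$dose_gy else acc
  if (length(doses) == 0) stop("empty target: no voxel doses")
  if (is.null(prescription_gy)) {
    if (!inherits(acc, "accumulated_dose")) {
      stop("'prescription_gy' is required for a bare dose vector")
    }
    prescription_gy <- acc$prescription_gy
  }
  if (x_percent <= 0 || x_percent > 100) stop("'x_percent' must be in (0, 100]")
  sorted <- sort(doses, decreasing = TRUE)
  rank <- ceiling(x_percent / 100 * length(sorted))
  100 * sorted[rank] / prescription_gy
}

#' Cumulative dose-volume histogram
#'
#' Fraction of target volume receiving at least each dose level, on a
#' uniform grid of dose percentages.
#'
#' @inheritParams dose_at_volume
#' @param dose_pct_grid dose levels (percent of prescription) to evaluate.
#' @return data.frame with columns `dose_pct` and `volume_fraction`
#'   (monotone non-increasing, starting at 1 for dose 0).
#' @export
dvh_curve <- function(acc, prescription_gy = NULL,
                      dose_pct_grid = seq(0, 130, by = 0.5)) {
  doses <- if (inherits(acc, "accumulated_dose")) acc$dose_gy else acc
  if (is.null(prescription_gy)) prescription_gy <- acc$prescription_gy
  pct <- 100 * doses / prescription_gy
  vol <- vapply(dose_pct_grid, function(d) mean(pct >= d), numeric(1))
  data.frame(dose_pct = dose_pct_grid, volume_fraction = vol)
}
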