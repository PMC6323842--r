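#' Treatment plan specification
#'
#' Parameters of the parametric plan-dose surrogate. The plan delivers the
#' prescription as the minimum ITV dose, with the ITV surface lying on the
#' chosen isodose level of the in-ITV maximum (`D_max =
#' prescription/isodose_level`), a flat central plateau reached
#' `core_depth_mm` inside the ITV, and a Gaussian penumbra of scale
#' `penumbra_sigma_mm` outside.
#'
#' @param prescription_gy total prescription dose (Gy; 60 Gy default).
#' @param n_fractions number of fractions (5 default).
#' @param isodose_level prescription as a fraction of the ITV maximum dose,
#'   in (0, 1); 0.70 / 0.80 / 0.90 are the study's levels.
#' @param core_depth_mm depth inside the ITV at which dose reaches its
#'   maximum (mm).
#' @param penumbra_sigma_mm Gaussian fall-off scale outside the ITV (mm).
#'   The exterior 80%-to-20% fall-off distance is
#'   `(sqrt(2 log 5) - sqrt(2 log 1.25)) * sigma ~= 1.13 * sigma`.
#' @return an object of class `plan_spec`.
#' @export
plan_spec <- function(prescription_gy = 60, n_fractions = 5,
                      isodose_level = 0.80, core_depth_mm = 5,
                      penumbra_sigma_mm = 3) {
  stop_if_not_scalar_number(prescription_gy, "prescription_gy")
  stop_if_not_scalar_number(isodose_level, "isodose_level")
  if (prescription_gy <= 0) stop("'prescription_gy' must be > 0")
  if (isodose_level <= 0 || isodose_level >= 1) {
    stop("'isodose_level' must be in (0, 1)")
  }
  if (core_depth_mm <= 0) stop("'core_depth_mm' must be > 0")
  if (penumbra_sigma_mm <= 0) stop("'penumbra_sigma_mm' must be > 0")
  structure(
    list(prescription_gy = prescription_gy,
         n_fractions = as.integer(n_fractions),
         isodose_level = isodose_level,
         core_depth_mm = core_depth_mm,
         penumbra_sigma_mm = penumbra_sigma_mm),
    class = "plan_spec"
  )
}

#' @export
print.plan_spec <- function(x, ...) {
  cat(sprintf(
    "Plan: %g Gy / %d fx, ITV on the %d%% isodose (D_max %.1f Gy), core %g mm, penumbra sigma %g mm\n",
    x$prescription_gy, x$n_fractions, round(100 * x$isodose_level),
    x$prescription_gy / x$isodose_level, x$core_depth_mm, x$penumbra_sigma_mm
  ))
  invisible(x)
}

#' Signed distance to the ITV surface
#'
#' Euclidean distance transform of the mask and of its complement, combined
#' into a signed distance in mm with the surface passing through the centers
#' of the outermost mask voxel layer: a boundary mask voxel has `s = 0`,
#' deeper voxels `s < 0`, and the first voxel ring outside the mask `s = 1`
#' voxel. This convention puts the mask surface voxels exactly on the
#' prescription isodose while keeping the `s` spacing across the interface
#' equal to the voxel pitch.
#'
#' @param mask a `volume_mask`.
#' @return numeric array of signed distances (mm), negative inside.
#' @export
signed_distance_mm <- function(mask) {
  stopifnot(inherits(mask, "volume_mask"))
  m <- mask$mask
  dims <- dim(m)
  d_in <- edt3d(m, dims)        # distance to nearest mask voxel (0 inside)
  d_out <- edt3d(!m, dims)      # distance to nearest complement voxel
  s <- ifelse(m, -(d_out - 1), d_in)
  array(s * mask$grid$voxel_mm, dim = dims)
}

new_dose_field <- function(dose, grid, spec, itv) {
  structure(list(dose = dose, grid = grid, spec = spec, itv = itv),
            class = "dose_field")
}

#' @export
print.dose_field <- function(x, ...) {
  dv <- x$dose[x$itv$mask]
  cat(sprintf(
    "Dose field: %g Gy prescription, in-ITV dose [%.2f, %.2f] Gy\n",
    x$spec$prescription_gy, min(dv), max(dv)
  ))
  invisible(x)
}

#' Parametric plan-dose surrogate
#'
#' Produces a static 3D dose field reproducing the dosimetric structure of
#' the clinical VMAT plans it stands in for: minimum ITV dose equal to the
#' prescription, the ITV surface on the `isodose_level` isodose of the
#' maximum, a flat plateau `D_max = prescription/isodose_level` deeper than
#' `core_depth_mm` inside the ITV, and a Gaussian penumbra outside. With
#' signed surface distance `s` (negative inside),
#' \deqn{D(s \le 0) = D_{max} (L + (1 - L) \min(1, -s/c)), \quad
#'       D(s > 0) = R_x e^{-s^2 / 2\sigma^2}}
#' where `L` is the isodose level, `c` the core depth, `Rx` the
#' prescription.
#'
#' @param itv a `volume_mask` (role ITV) to plan on.
#' @param spec a [plan_spec()].
#' @return a `dose_field` holding the dose array, grid, spec and ITV.
#' @export
plan_dose <- function(itv, spec) {
  stopifnot(inherits(itv, "volume_mask"), inherits(spec, "plan_spec"))
  if (!any(itv$mask)) stop("ITV mask is empty")
  s <- signed_distance_mm(itv)
  dmax <- spec$prescription_gy / spec$isodose_level
  lvl <- spec$isodose_level
  inside <- s <= 0
  dose <- numeric(length(s))
  dose[inside] <- dmax * (lvl + (1 - lvl) *
                            pmin(1, -s[inside] / spec$core_depth_mm))
  dose[!inside] <- spec$prescription_gy *
    exp(-s[!inside]^2 / (2 * spec$penumbra_sigma_mm^2))
  new_dose_field(array(dose, dim = dim(s)), itv$grid, spec, itv)
}

#' Robust plan from the position-pdf coverage interval
#'
#' Extends the traditional phase-position set with every integer position in
#' the pdf coverage interval (clamped to the phantom's -15..15 mm range),
#' rebuilds the ITV over the extended set and re-plans on it. With a
#' coverage interval already inside the traditional range the plan is
#' unchanged.
#'
#' @param traditional_positions integer SI positions (mm) of the traditional
#'   ten-phase 4DCT.
#' @param pdf_interval length-2 interval `(lo, hi)` in mm, e.g. from
#'   [coverage_interval()].
#' @param diameter_cm target sphere diameter (cm).
#' @param grid a [phantom_grid()].
#' @param spec a [plan_spec()].
#' @return a `dose_field`; the extended position set is attached as
#'   attribute `positions_mm` (and on its `$itv`).
#' @export
robust_plan_dose <- function(traditional_positions, pdf_interval,
                             diameter_cm, grid, spec) {
  stopifnot(length(pdf_interval) == 2)
  lo <- pdf_interval[1]
  hi <- pdf_interval[2]
  if (lo < -15 || hi > 15) {
    warning("coverage interval exceeds the phantom range; clamped to [-15, 15]")
    lo <- max(lo, -15)
    hi <- min(hi, 15)
  }
  extended <- sort(unique(c(as.integer(traditional_positions),
                            seq(as.integer(lo), as.integer(hi)))))
  itv <- build_itv(grid, diameter_cm, extended)
  field <- plan_dose(itv, spec)
  attr(field, "positions_mm") <- extended
  field
}
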