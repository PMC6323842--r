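#' Voxel grid of the digital lung-tumor phantom
#'
#' Isotropic voxel grid holding the spherical target masks and the plan-dose
#' surrogate. The superior-inferior (SI) axis is the one the tumor moves
#' along; the grid must span the largest sphere (4 cm) plus the +-15 mm
#' motion range.
#'
#' @param shape integer vector of voxel counts `(nx, ny, nz)`.
#' @param voxel_mm isotropic voxel edge length (mm, default 1).
#' @param si_axis which array index is SI (default 3).
#' @param origin_mm mm coordinates of voxel (1,1,1) center; by default the
#'   grid is centered on 0 so the reference sphere center sits mid-grid.
#' @return an object of class `phantom_grid`.
#' @export
phantom_grid <- function(shape = c(120L, 120L, 120L), voxel_mm = 1,
                         si_axis = 3L, origin_mm = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0), voxel_mm > 0,
            si_axis %in% 1:3)
  if (shape[si_axis] * voxel_mm < 70) {
    stop("SI extent must be at least 70 mm (40 mm sphere + 15 mm travel each way)")
  }
  if (is.null(origin_mm)) {
    origin_mm <- -(shape - 1) / 2 * voxel_mm
  }
  structure(
    list(shape = shape, voxel_mm = voxel_mm, si_axis = as.integer(si_axis),
         origin_mm = origin_mm),
    class = "phantom_grid"
  )
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat(sprintf("Phantom grid %d x %d x %d voxels at %g mm (SI axis %d)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_mm, x$si_axis))
  invisible(x)
}

# mm coordinates of every voxel center along each axis
grid_axes_mm <- function(grid) {
  lapply(1:3, function(a) grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$voxel_mm)
}

#' Spherical target geometry
#'
#' A spherical gross target volume (GTV) of 2, 3 or 4 cm diameter, displaced
#' along SI by an integer offset in -15..15 mm from the reference position
#' (the sphere center at offset 0, the grid origin).
#'
#' @param diameter_cm sphere diameter in cm.
#' @param si_offset_mm integer SI offset in mm, within -15..15.
#' @return an object of class `target_geometry`.
#' @export
target_geometry <- function(diameter_cm, si_offset_mm = 0) {
  stop_if_not_scalar_number(diameter_cm, "diameter_cm")
  if (diameter_cm <= 0) stop("'diameter_cm' must be positive")
  if (length(si_offset_mm) != 1 || si_offset_mm != round(si_offset_mm) ||
      abs(si_offset_mm) > 15) {
    stop("'si_offset_mm' must be an integer in [-15, 15]")
  }
  structure(
    list(diameter_cm = diameter_cm, si_offset_mm = as.integer(si_offset_mm)),
    class = "target_geometry"
  )
}

new_volume_mask <- function(mask, grid, role) {
  structure(list(mask = mask, grid = grid, role = role),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("%s mask: %d voxels (%.2f cm^3)\n", x$role, sum(x$mask),
              sum(x$mask) * x$grid$voxel_mm^3 / 1000))
  invisible(x)
}

#' Voxelize a spherical GTV
#'
#' A voxel belongs to the GTV iff its center lies within `diameter/2` of the
#' sphere center displaced by `si_offset_mm` along the SI axis (no
#' partial-volume weighting).
#'
#' @param grid a [phantom_grid()].
#' @param geom a [target_geometry()].
#' @return a `volume_mask` with role `"GTV"`.
#' @export
make_gtv_mask <- function(grid, geom) {
  stopifnot(inherits(grid, "phantom_grid"), inherits(geom, "target_geometry"))
  r <- geom$diameter_cm * 10 / 2
  center <- c(0, 0, 0)
  center[grid$si_axis] <- geom$si_offset_mm
  ax <- grid_axes_mm(grid)
  for (a in 1:3) {
    if (center[a] - r < min(ax[[a]]) - grid$voxel_mm / 2 ||
        center[a] + r > max(ax[[a]]) + grid$voxel_mm / 2) {
      stop("sphere at this offset does not fit inside the grid")
    }
  }
  d1 <- (ax[[1]] - center[1])^2
  d2 <- (ax[[2]] - center[2])^2
  d3 <- (ax[[3]] - center[3])^2
  mask <- outer(outer(d1, d2, "+"), d3, "+") <= r^2
  new_volume_mask(mask, grid, "GTV")
}

#' Map an SI position to its 4DCT phase index
#'
#' The phantom's 31 sample positions (SI = -15..15 mm) are binned to the ten
#' respiratory phases by `floor((i + 15)/3)`, with the topmost position
#' `i = 15` assigned to phase 9.
#'
#' @param i integer SI position(s) in mm, each within -15..15.
#' @return integer phase index/indices in 0..9.
#' @export
map_si_to_phase <- function(i) {
  if (any(i != round(i)) || any(abs(i) > 15)) {
    stop("'i' must be integer mm within [-15, 15]")
  }
  ifelse(i == 15, 9L, as.integer(floor((i + 15) / 3)))
}

#' Build an internal target volume (ITV)
#'
#' Union of the GTV masks over a set of SI positions, mirroring the clinical
#' construction of the ITV as the union of all phase GTVs.
#'
#' @param grid a [phantom_grid()].
#' @param diameter_cm sphere diameter in cm.
#' @param positions_mm non-empty set of integer SI positions (mm).
#' @return a `volume_mask` with role `"ITV"`; the position set is attached
#'   as attribute `positions_mm`.
#' @export
build_itv <- function(grid, diameter_cm, positions_mm) {
  if (length(positions_mm) == 0) stop("'positions_mm' must be non-empty")
  positions_mm <- sort(unique(as.integer(positions_mm)))
  mask <- NULL
  for (p in positions_mm) {
    g <- make_gtv_mask(grid, target_geometry(diameter_cm, p))
    mask <- if (is.null(mask)) g$mask else (mask | g$mask)
  }
  out <- new_volume_mask(mask, grid, "ITV")
  attr(out, "positions_mm") <- positions_mm
  out
}

#' Enumerate the 93-image phantom sample bank
#'
#' One entry per (sphere diameter, SI position) pair: 31 positions from -15
#' to 15 mm times 3 diameters = 93 sample images, each tagged with its
#' respiratory phase via [map_si_to_phase()]. Masks are built lazily with
#' [make_gtv_mask()]; the bank itself is bookkeeping.
#'
#' @param grid a [phantom_grid()].
#' @param diameters_cm sphere diameters (cm).
#' @param positions_mm integer SI positions (mm).
#' @return data.frame with columns `diameter_cm`, `si_mm`, `phase`.
#' @export
build_sample_bank <- function(grid = phantom_grid(),
                              diameters_cm = c(2, 3, 4),
                              positions_mm = -15:15) {
  bank <- expand.grid(si_mm = as.integer(positions_mm),
                      diameter_cm = diameters_cm)
  bank$phase <- map_si_to_phase(bank$si_mm)
  bank[, c("diameter_cm", "si_mm", "phase")]
}

#' Export a mask or dose array as NIfTI
#'
#' Optional convenience export through the RNifti package.
#'
#' @param x a `volume_mask` or `dose_field`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export")
  }
  arr <- if (inherits(x, "volume_mask")) array(as.numeric(x$mask), dim = x$grid$shape)
  else if (inherits(x, "dose_field")) x$dose
  else stop("'x' must be a volume_mask or dose_field")
  vox <- if (inherits(x, "volume_mask")) x$grid$voxel_mm else x$grid$voxel_mm
  img <- RNifti::asNifti(arr, pixdim = rep(vox, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
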