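# Voxelized activity/attenuation phantoms.
#
# Grid convention: x = tangential, y = ray direction toward the detector
# (at view angle 0), z = axial.  Voxels are cubes of `voxel_mm`; the grid
# is centred on the phantom axis.

#' Construct a phantom specification
#'
#' @param activity Named list of 3-D activity arrays (kBq/ml), one per
#'   isotope (names `"Tc-99m"`, `"I-123"`).
#' @param mu 3-D linear attenuation map in mm^-1 at the reference energy
#'   (141 keV); the simulator rescales it with energy via [water_mu()].
#' @param voxel_mm Isotropic voxel size in mm.
#' @param name Phantom label.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(activity, mu, voxel_mm, name = "phantom") {
  stopifnot(is.list(activity), length(activity) >= 1L,
            !is.null(names(activity)))
  dims <- lapply(activity, dim)
  if (!all(vapply(dims, identical, logical(1), dim(mu)))) {
    stop("activity and attenuation grids must be congruent")
  }
  for (a in activity) if (any(a < 0)) stop("activities must be >= 0")
  if (any(mu < 0)) stop("attenuation must be >= 0")
  structure(list(activity = activity, mu = mu, voxel_mm = voxel_mm,
                 name = name),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>", x$name, ":",
      paste(dim(x$mu), collapse = " x "), "voxels @", x$voxel_mm, "mm\n")
  for (iso in names(x$activity)) {
    a <- x$activity[[iso]]
    cat(sprintf("  %s: total %.4g kBq/ml-voxels, max %.4g kBq/ml\n",
                iso, sum(a), max(a)))
  }
  invisible(x)
}

# Voxel-centre coordinate vectors (mm), grid centred at the origin.
grid_coords <- function(n, voxel_mm) (seq_len(n) - (n + 1) / 2) * voxel_mm

default_grid_n <- function(extent_mm, voxel_mm, margin = 1.25) {
  n <- ceiling(extent_mm * margin / voxel_mm)
  n + n %% 2L  # even
}

#' Uniform cylindrical phantom
#'
#' Water-filled circular cylinder (axis along z) with uniform activity
#' concentrations; attenuation is the water value inside and zero outside.
#'
#' @param inner_diameter Cylinder inner diameter in mm.
#' @param length Cylinder length in mm.
#' @param activity_tc,activity_i Uniform activity concentrations in kBq/ml.
#' @param voxel_mm Voxel size in mm.
#' @param mu Attenuation coefficient inside the cylinder, mm^-1.
#' @param nxy,nz Optional grid dimensions (derived from the geometry when
#'   `NULL`).
#' @return A [phantom_spec()].
#' @export
make_cylinder_phantom <- function(inner_diameter = 200, length = 200,
                                  activity_tc = 1, activity_i = 0,
                                  voxel_mm = 4, mu = 0.015,
                                  nxy = NULL, nz = NULL) {
  stopifnot(inner_diameter > 0, length > 0)
  if (is.null(nxy)) nxy <- default_grid_n(inner_diameter, voxel_mm)
  if (is.null(nz)) nz <- default_grid_n(length, voxel_mm, margin = 1)
  x <- grid_coords(nxy, voxel_mm); z <- grid_coords(nz, voxel_mm)
  r2 <- outer(x^2, x^2, `+`)
  in_xy <- r2 <= (inner_diameter / 2)^2
  in_z <- abs(z) <= length / 2
  mask <- array(0, dim = c(nxy, nxy, nz))
  for (k in which(in_z)) mask[, , k] <- in_xy
  phantom_spec(
    activity = list("Tc-99m" = activity_tc * mask,
                    "I-123" = activity_i * mask),
    mu = mu * mask, voxel_mm = voxel_mm, name = "cylinder"
  )
}

#' Line-source phantom
#'
#' Thin cylinder (default 10 mm diameter, 100 mm length) in air, used for
#' scatter-free detector-response measurements.
#'
#' @inheritParams make_cylinder_phantom
#' @param diameter Source diameter in mm.
#' @param mu Attenuation inside the source (default 0: scatter-free).
#' @export
make_line_phantom <- function(diameter = 10, length = 100,
                              activity_tc = 1, activity_i = 0,
                              voxel_mm = 4, mu = 0, nxy = NULL, nz = NULL) {
  if (is.null(nxy)) nxy <- default_grid_n(max(diameter, 40), voxel_mm)
  p <- make_cylinder_phantom(inner_diameter = diameter, length = length,
                             activity_tc = activity_tc,
                             activity_i = activity_i,
                             voxel_mm = voxel_mm, mu = mu,
                             nxy = nxy, nz = nz)
  p$name <- "line"
  p
}

#' Default six-compartment activity table
#'
#' Activity concentrations (kBq/ml) of the six-compartment brain phantom:
#' nominal Tc:I target ratios 3:1, 0:4, 4:0, 2:2, 0:0 and 1:3 across
#' compartments 1--6.
#' @return data.frame with columns `compartment`, `volume_ml`, `tc_kbq_ml`,
#'   `i_kbq_ml`.
#' @export
six_compartment_activities <- function() {
  data.frame(
    compartment = 1:6,
    volume_ml = c(120, 120, 120, 100, 100, 120),
    tc_kbq_ml = c(295, 0, 411, 201, 0, 96),
    i_kbq_ml = c(95, 372, 0, 186, 0, 278)
  )
}

#' Six-compartment elliptic phantom
#'
#' Elliptic cylinder (outside major diameter 186 mm, minor 130 mm, length
#' 50 mm) divided into six 60-degree wedge compartments around its axis,
#' filled with the activities of [six_compartment_activities()] by default.
#' Compartment `i` occupies polar angles `[(i-1)*60, i*60)` degrees
#' measured from the +x axis.
#'
#' @param activities Data frame in the format of
#'   [six_compartment_activities()].
#' @param voxel_mm Voxel size in mm.
#' @param major,minor,length Outside diameters and length in mm.
#' @param mu Attenuation inside, mm^-1.
#' @param nxy,nz Optional grid dimensions.
#' @return A [phantom_spec()] with a `compartments` field (integer label
#'   array, 0 outside).
#' @export
make_six_compartment_phantom <- function(activities =
                                           six_compartment_activities(),
                                         voxel_mm = 4,
                                         major = 186, minor = 130,
                                         length = 50, mu = 0.015,
                                         nxy = NULL, nz = NULL) {
  if (is.null(nxy)) nxy <- default_grid_n(major, voxel_mm)
  if (is.null(nz)) nz <- default_grid_n(length, voxel_mm, margin = 1)
  x <- grid_coords(nxy, voxel_mm)
  a <- major / 2; b <- minor / 2
  X <- matrix(x, nxy, nxy); Y <- matrix(x, nxy, nxy, byrow = TRUE)
  inside <- (X / a)^2 + (Y / b)^2 <= 1
  ang <- (atan2(Y, X) * 180 / pi) %% 360
  comp_xy <- ifelse(inside, pmin(floor(ang / 60) + 1L, 6L), 0L)
  z <- grid_coords(nz, voxel_mm)
  in_z <- abs(z) <= length / 2
  comp <- array(0L, dim = c(nxy, nxy, nz))
  for (k in which(in_z)) comp[, , k] <- comp_xy
  tc <- array(0, dim = dim(comp)); iod <- tc
  for (i in 1:6) {
    sel <- comp == i
    tc[sel] <- activities$tc_kbq_ml[i]
    iod[sel] <- activities$i_kbq_ml[i]
  }
  p <- phantom_spec(activity = list("Tc-99m" = tc, "I-123" = iod),
                    mu = mu * (comp > 0), voxel_mm = voxel_mm,
                    name = "six-compartment")
  p$compartments <- comp
  p$geometry <- list(major = major, minor = minor, length = length)
  p$activities <- activities
  p
}

#' Total phantom activity
#'
#' Sums the activity concentration over the voxel grid, giving the total
#' activity per isotope in MBq.
#'
#' @param phantom A [phantom_spec()].
#' @return Named numeric vector of total activities in MBq.
#' @export
total_activity_mbq <- function(phantom) {
  voxel_ml <- phantom$voxel_mm^3 / 1000
  vapply(phantom$activity, function(a) sum(a) * voxel_ml / 1000,
         numeric(1))
}

#' Water linear attenuation coefficient
#'
#' Narrow-beam linear attenuation of water, mm^-1, interpolated log-log
#' from tabulated mass-attenuation values.  Used by the simulator to scale
#' the phantom attenuation map with photon energy.
#'
#' @param energy_kev Photon energy in keV (vectorized).
#' @return Attenuation coefficient(s) in mm^-1.
#' @export
water_mu <- function(energy_kev) {
  # mu/rho (cm^2/g) for water at selected energies, standard tabulations
  e <- c(30, 40, 50, 60, 80, 100, 150, 200, 300, 400, 500, 600)
  mu_rho <- c(0.3756, 0.2683, 0.2269, 0.2059, 0.1837, 0.1707,
              0.1505, 0.1370, 0.1186, 0.1061, 0.09687, 0.08956)
  lmu <- stats::approx(log(e), log(mu_rho), xout = log(energy_kev),
                       rule = 2)$y
  exp(lmu) * 0.1  # rho = 1 g/cm^3; cm^-1 -> mm^-1
}

#' Scanner acquisition specification
#'
#' Defaults describe the prototype two-head CdTe brain scanner: 192 x 96
#' detector pixels at 1.4 mm pitch, wide-aperture parallel-hole collimator
#' (hole 2.4 mm, pitch 2.8 mm, length 26 mm), 130 mm rotation radius, 120
#' views over 360 degrees.
#'
#' @param n_tan,n_ax Detector pixels (tangential x axial).
#' @param pixel_mm Pixel pitch in mm.
#' @param rotation_radius Collimator-face-to-axis distance in mm.
#' @param n_views Number of projection views.
#' @param arc Total rotation arc in degrees.
#' @param hole_mm,hole_pitch_mm,collimator_mm Collimator hole size, pitch
#'   and length in mm.
#' @param duration_s Acquisition duration in seconds.
#' @param seed Default random seed for simulations using this spec.
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(n_tan = 192, n_ax = 96, pixel_mm = 1.4,
                             rotation_radius = 130, n_views = 120,
                             arc = 360, hole_mm = 2.4, hole_pitch_mm = 2.8,
                             collimator_mm = 26, duration_s = 180,
                             seed = 1L) {
  stopifnot(n_tan >= 1, n_ax >= 1, pixel_mm > 0, rotation_radius > 0,
            n_views >= 1, arc > 0, hole_mm > 0, collimator_mm > 0)
  structure(list(n_tan = as.integer(n_tan), n_ax = as.integer(n_ax),
                 pixel_mm = pixel_mm, rotation_radius = rotation_radius,
                 n_views = as.integer(n_views), arc = arc,
                 hole_mm = hole_mm, hole_pitch_mm = hole_pitch_mm,
                 collimator_mm = collimator_mm, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' View angles of an acquisition
#' @param acq An [acquisition_spec()].
#' @return Numeric vector of view angles in degrees.
#' @export
view_angles <- function(acq) {
  acq$arc * (seq_len(acq$n_views) - 1L) / acq$n_views
}
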