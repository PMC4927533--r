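# ROI definition and quantitative phantom metrics.

#' Region-of-interest set
#'
#' @param masks Named list of logical 3-D masks on a common volume grid.
#' @param geometry Optional data frame describing each ROI (centre, radius,
#'   length, labels).
#' @return An `roi_set` object.
#' @export
roi_set <- function(masks, geometry = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1L, !is.null(names(masks)))
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all ROI masks must share one grid")
  }
  n <- vapply(masks, sum, numeric(1))
  if (any(n == 0)) {
    stop("empty ROI mask(s): ", paste(names(masks)[n == 0], collapse = ", "))
  }
  structure(list(masks = masks, geometry = geometry), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> with", length(x$masks), "ROIs on a",
      paste(dim(x$masks[[1]]), collapse = " x "), "grid\n")
  invisible(x)
}

cylinder_mask <- function(dim_vol, voxel_mm, center_mm, radius_mm,
                          length_mm) {
  x <- grid_coords(dim_vol[1], voxel_mm)
  y <- grid_coords(dim_vol[2], voxel_mm)
  z <- grid_coords(dim_vol[3], voxel_mm)
  in_xy <- outer((x - center_mm[1])^2, (y - center_mm[2])^2, `+`) <=
    radius_mm^2
  in_z <- abs(z - center_mm[3]) <= length_mm / 2
  mask <- array(FALSE, dim_vol)
  for (k in which(in_z)) mask[, , k] <- in_xy
  mask
}

#' ROIs of the uniform cylinder phantom
#'
#' Cylindrical ROIs (default 20 mm diameter, 100 mm length) placed at
#' radii 25, 50 and 70 mm from the phantom centre, six per radius every 60
#' degrees: 18 ROIs in total.
#'
#' @param dim_vol Volume dimensions `c(nx, ny, nz)`.
#' @param voxel_mm Voxel size in mm.
#' @param radii_mm Radii of the ROI rings.
#' @param n_per_ring ROIs per ring.
#' @param roi_diameter_mm,roi_length_mm ROI cylinder geometry.
#' @return An [roi_set()].
#' @export
uniform_phantom_rois <- function(dim_vol, voxel_mm,
                                 radii_mm = c(25, 50, 70),
                                 n_per_ring = 6,
                                 roi_diameter_mm = 20,
                                 roi_length_mm = 100) {
  extent <- dim_vol[1:2] * voxel_mm / 2
  if (any(max(radii_mm) + roi_diameter_mm / 2 > extent)) {
    stop("grid too small for the requested ROI radii")
  }
  masks <- list()
  geom <- NULL
  for (r in radii_mm) {
    for (k in seq_len(n_per_ring)) {
      ang <- 2 * pi * (k - 1) / n_per_ring
      ctr <- c(r * cos(ang), r * sin(ang), 0)
      nm <- sprintf("r%g_a%d", r, k)
      masks[[nm]] <- cylinder_mask(dim_vol, voxel_mm, ctr,
                                   roi_diameter_mm / 2, roi_length_mm)
      geom <- rbind(geom, data.frame(roi = nm, radius_mm = r,
                                     angle_deg = ang * 180 / pi,
                                     x = ctr[1], y = ctr[2], z = 0))
    }
  }
  roi_set(masks, geom)
}

#' ROIs of the six-compartment phantom
#'
#' Three cylindrical ROIs (default 14 mm diameter) per wedge compartment,
#' placed on the wedge bisector: at the compartment centroid and displaced
#' by +-`offset_frac` of the centroid-to-boundary distance.  This fixed
#' three-ROI-per-compartment layout gives 18 ROIs.
#'
#' @param phantom A six-compartment [phantom_spec()] (provides the wedge
#'   geometry), or `NULL` to use the default geometry.
#' @param dim_vol Volume dimensions.
#' @param voxel_mm Voxel size in mm.
#' @param roi_diameter_mm ROI diameter.
#' @param roi_length_mm ROI length (defaults to 60 % of the phantom
#'   length).
#' @param offset_frac Radial displacement of the off-centre ROIs.
#' @return An [roi_set()] whose geometry table carries the compartment of
#'   each ROI.
#' @export
six_compartment_rois <- function(dim_vol, voxel_mm, phantom = NULL,
                                 roi_diameter_mm = 14,
                                 roi_length_mm = NULL,
                                 offset_frac = 0.6) {
  geo <- if (!is.null(phantom) && !is.null(phantom$geometry)) {
    phantom$geometry
  } else list(major = 186, minor = 130, length = 50)
  if (is.null(roi_length_mm)) roi_length_mm <- 0.6 * geo$length
  a <- geo$major / 2; b <- geo$minor / 2
  masks <- list()
  geom <- NULL
  for (comp in 1:6) {
    bis <- (comp - 0.5) * 60 * pi / 180  # wedge bisector angle
    u <- c(cos(bis), sin(bis))
    # boundary of the ellipse along the bisector
    rb <- 1 / sqrt((u[1] / a)^2 + (u[2] / b)^2)
    # area centroid of a thin wedge lies ~2/3 of the way out
    rc <- 2 / 3 * rb
    for (j in 1:3) {
      rj <- rc + (j - 2) * offset_frac * (rb - rc)
      rj <- min(rj, rb - roi_diameter_mm / 2 - voxel_mm)
      ctr <- c(rj * u[1], rj * u[2], 0)
      nm <- sprintf("c%d_%d", comp, j)
      masks[[nm]] <- cylinder_mask(dim_vol, voxel_mm, ctr,
                                   roi_diameter_mm / 2, roi_length_mm)
      geom <- rbind(geom, data.frame(roi = nm, compartment = comp,
                                     x = ctr[1], y = ctr[2], z = 0))
    }
  }
  roi_set(masks, geom)
}

#' Per-ROI mean and standard deviation
#'
#' @param vol A [spect_volume()] or 3-D array.
#' @param rois An [roi_set()] on the same grid.
#' @return data.frame with columns `roi`, `mean`, `sd`, `n_voxels`, joined
#'   with the ROI geometry table when available.
#' @export
roi_stats <- function(vol, rois) {
  v <- as_volume_array(vol)
  if (!identical(dim(v), dim(rois$masks[[1]]))) {
    stop("volume and ROI grids do not match")
  }
  df <- data.frame(
    roi = names(rois$masks),
    mean = vapply(rois$masks, function(m) mean(v[m]), numeric(1)),
    sd = vapply(rois$masks, function(m) stats::sd(v[m]), numeric(1)),
    n_voxels = vapply(rois$masks, sum, numeric(1)),
    row.names = NULL
  )
  if (!is.null(rois$geometry)) df <- merge(df, rois$geometry, by = "roi",
                                           sort = FALSE)
  df
}

#' Cross-calibration factor
#'
#' Factor converting reconstructed voxel units into activity concentration,
#' obtained by dividing the true activity (well-counter value) by the mean
#' ROI voxel value of a uniform-phantom acquisition.  Factors are computed
#' per correction method and per radionuclide.
#'
#' @param mean_roi_value Mean reconstructed voxel value (must be > 0).
#' @param true_activity True activity concentration, kBq/ml.
#' @return Calibration factor in kBq/ml per voxel unit.
#' @export
cross_calibrate <- function(mean_roi_value, true_activity) {
  if (any(mean_roi_value <= 0)) stop("mean ROI value must be positive")
  true_activity / mean_roi_value
}

#' Percentage error against a reference
#'
#' `100 * |measured - reference| / reference`; used both for the
#' corrected-vs-primary planar comparisons and (as "percentage
#' difference", PD) for ROI-vs-injected-activity comparisons.
#'
#' @param measured,reference Numeric (vectorized); `reference > 0`.
#' @return Percent values.
#' @export
percentage_error <- function(measured, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * abs(measured - reference) / reference
}

#' @rdname percentage_error
#' @export
percent_difference <- percentage_error

#' Relative percentage difference of standardized hot-ROI values
#'
#' Hot-ROI values and injected activities are each standardized by the
#' compartment with the highest injected activity of the radionuclide of
#' interest; the PD between the standardized measured values and the
#' injected activity ratios is returned.
#'
#' @param measured Hot-ROI values (one per hot compartment).
#' @param injected Injected activities for the same compartments.
#' @param reference_idx Index of the standardization compartment within the
#'   vectors (default: the highest injected activity).
#' @return Percent values (the reference entry is 0 by construction).
#' @export
relative_percent_difference <- function(measured, injected,
                                        reference_idx =
                                          which.max(injected)) {
  stopifnot(length(measured) == length(injected))
  if (measured[reference_idx] <= 0) stop("reference measurement must be > 0")
  std_meas <- measured / measured[reference_idx]
  std_inj <- injected / injected[reference_idx]
  percentage_error(std_meas, std_inj)
}

#' Residual scatter
#'
#' Mean cold-ROI value divided by mean hot-ROI value, in percent.  Defined
#' only when both cold and hot ROIs exist.
#'
#' @param cold_values Voxel means of ROIs in zero-activity compartments.
#' @param hot_values Voxel means of ROIs in active compartments.
#' @return RS in percent.
#' @export
residual_scatter <- function(cold_values, hot_values) {
  if (!length(hot_values)) stop("residual scatter needs at least one hot ROI")
  if (!length(cold_values)) stop("residual scatter needs at least one cold ROI")
  100 * mean(cold_values) / mean(hot_values)
}

#' Physical decay correction
#'
#' Scales counts back to acquisition start: `counts * 2^(elapsed / T_half)`.
#' Half-lives are physical constants (Tc-99m 6.007 h, I-123 13.22 h).
#'
#' @param counts Measured counts.
#' @param elapsed_s Elapsed time in seconds (>= 0).
#' @param isotope `"Tc-99m"` or `"I-123"`.
#' @return Decay-corrected counts.
#' @export
decay_correct <- function(counts, elapsed_s, isotope) {
  stopifnot(elapsed_s >= 0)
  half_life_s <- switch(isotope,
                        "Tc-99m" = 6.007 * 3600,
                        "I-123" = 13.22 * 3600,
                        stop("unknown isotope '", isotope, "'"))
  counts * 2^(elapsed_s / half_life_s)
}

#' Linearity of estimated vs injected activity
#'
#' Least-squares regression of estimated compartment activities on the
#' injected activities; reports slope, intercept and R^2.
#'
#' @param estimated,injected Numeric vectors (one value per compartment).
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
activity_linearity <- function(estimated, injected) {
  stopifnot(length(estimated) == length(injected), length(injected) >= 2)
  fit <- stats::lm(estimated ~ injected)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
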