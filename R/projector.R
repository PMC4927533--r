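# Rotation-based forward and backward projectors.
#
# A projection view at angle phi is formed by rotating the volume (and the
# attenuation map) by -phi about the axial (z) axis so that the detector
# lies along +y, attenuating each voxel by the exponential of the line
# integral from the voxel to the detector, optionally convolving each
# constant-distance plane with the distance-dependent collimator PSF, and
# summing along y.  Rotation is a sparse linear operator (bilinear
# interpolation), so the back projector is its exact transpose and the
# forward/back pair is adjoint to machine precision.

.fiveew_cache <- new.env(parent = emptyenv())

#' Sparse in-plane rotation operator
#'
#' Returns the `n^2 x n^2` sparse matrix that rotates an `n x n` image by
#' `angle_deg` degrees about its centre using bilinear interpolation
#' (values outside the grid are treated as zero).  Operators are cached.
#'
#' @param n Image side length in pixels.
#' @param angle_deg Rotation angle in degrees.
#' @return A `dgCMatrix` sparse operator.
#' @export
rotation_operator <- function(n, angle_deg) {
  key <- sprintf("rot_%d_%.6f", n, angle_deg %% 360)
  if (!is.null(.fiveew_cache[[key]])) return(.fiveew_cache[[key]])
  th <- angle_deg * pi / 180
  c0 <- (n + 1) / 2
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  xi <- ij$i - c0; yj <- ij$j - c0
  # sample the source image at the target coordinates rotated by -angle
  xs <- cos(th) * xi + sin(th) * yj + c0
  ys <- -sin(th) * xi + cos(th) * yj + c0
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  row <- rep(seq_len(n * n), 4L)
  sx <- c(x0, x0 + 1, x0, x0 + 1)
  sy <- c(y0, y0, y0 + 1, y0 + 1)
  wt <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  ok <- sx >= 1 & sx <= n & sy >= 1 & sy <= n & wt > 0
  R <- Matrix::sparseMatrix(i = row[ok],
                            j = (sy[ok] - 1L) * n + sx[ok],
                            x = wt[ok], dims = c(n * n, n * n))
  .fiveew_cache[[key]] <- R
  R
}

# Apply a rotation operator to a 3-D volume (rotates every z-slice).
rotate_volume <- function(vol, R) {
  d <- dim(vol)
  out <- as.matrix(R %*% matrix(vol, nrow = d[1] * d[2], ncol = d[3]))
  array(out, dim = d)
}

# Transposed application (exact adjoint of rotate_volume).
rotate_volume_t <- function(vol, R) {
  d <- dim(vol)
  out <- as.matrix(Matrix::crossprod(R, matrix(vol, nrow = d[1] * d[2],
                                               ncol = d[3])))
  array(out, dim = d)
}

# Attenuation factors in the rotated frame: for each voxel, exp(-integral
# of mu from the voxel centre to the detector side (+y, increasing second
# index)).
attenuation_factors <- function(mu_rot, voxel_mm) {
  d <- dim(mu_rot)
  path <- apply(mu_rot, c(1, 3), function(col) {
    rev(cumsum(rev(col))) - col / 2
  })
  # apply returns y index first: permute back to (x, y, z)
  exp(-voxel_mm * aperm(path, c(2, 1, 3)))
}

# Distance-dependent collimator PSF: Gaussian whose FWHM grows linearly
# with the source-to-collimator distance, FWHM(d) = hole * (L + d) / L
# from the aperture geometry (hole size, collimator length L).
psf_fwhm_mm <- function(dist_mm, acq) {
  acq$hole_mm * (acq$collimator_mm + pmax(dist_mm, 0)) / acq$collimator_mm
}

gaussian_kernel <- function(sigma_px, halfwidth = NULL) {
  if (sigma_px <= 1e-6) return(1)
  if (is.null(halfwidth)) halfwidth <- max(1L, ceiling(3 * sigma_px))
  x <- (-halfwidth):halfwidth
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Symmetric banded convolution matrix (zero boundary), self-adjoint.
conv_band_matrix <- function(n, kernel) {
  hw <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (o in -hw:hw) {
    idx <- seq_len(n)
    src <- idx + o
    ok <- src >= 1 & src <= n
    M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] +
      kernel[o + hw + 1L]
  }
  M
}

# Per-depth PSF operators for one view geometry (same for all views).
psf_operators <- function(d, acq, voxel_mm) {
  ny <- d[2]
  yc <- grid_coords(ny, voxel_mm)
  lapply(seq_len(ny), function(iy) {
    dist <- acq$rotation_radius - yc[iy]
    sig <- psf_fwhm_mm(dist, acq) / 2.35482 / voxel_mm
    kx <- gaussian_kernel(sig)
    list(Kx = conv_band_matrix(d[1], kx), Kz = conv_band_matrix(d[3], kx))
  })
}

apply_psf_plane <- function(plane, op) {
  if (length(op$Kx) == 1L && length(op$Kz) == 1L) return(plane)
  op$Kx %*% plane %*% t(op$Kz)
}

#' Attenuation map container
#'
#' @param mu 3-D linear attenuation array in mm^-1.
#' @param voxel_mm Voxel size in mm.
#' @return An `attenuation_map` object.
#' @export
attenuation_map <- function(mu, voxel_mm) {
  mu <- as.array(mu)
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("attenuation must be finite and >= 0")
  }
  structure(list(mu = mu, voxel_mm = voxel_mm), class = "attenuation_map")
}

#' Reconstructed volume container
#'
#' @param values 3-D activity array.
#' @param voxel_mm Voxel size in mm.
#' @return A `spect_volume` object.
#' @export
spect_volume <- function(values, voxel_mm) {
  structure(list(values = as.array(values), voxel_mm = voxel_mm),
            class = "spect_volume")
}

#' @export
print.spect_volume <- function(x, ...) {
  cat("<spect_volume>", paste(dim(x$values), collapse = " x "),
      "voxels @", x$voxel_mm, "mm; total", format(sum(x$values)), "\n")
  invisible(x)
}

as_volume_array <- function(vol) {
  if (inherits(vol, "spect_volume")) vol$values else as.array(vol)
}

#' Attenuated forward projection
#'
#' Projects a volume into a stack of views.  The volume must be square in
#' the transaxial plane (`nx == ny`) with `nx` matching the tangential
#' detector size and `nz` the axial size.
#'
#' @param vol A [spect_volume()] or 3-D array (x = tangential, y = ray
#'   direction, z = axial).
#' @param att An [attenuation_map()] on the same grid (or `NULL` for no
#'   attenuation).
#' @param acq An [acquisition_spec()]; `n_views` and `arc` define the view
#'   angles.
#' @param psf Model the distance-dependent collimator response.
#' @return 3-D array of projections (tangential x axial x view).
#' @export
forward_project <- function(vol, att, acq, psf = FALSE) {
  v <- as_volume_array(vol)
  d <- dim(v)
  stopifnot(d[1] == d[2])
  voxel_mm <- if (inherits(vol, "spect_volume")) vol$voxel_mm else
    acq$pixel_mm
  angles <- view_angles(acq)
  ops <- if (psf) psf_operators(d, acq, voxel_mm) else NULL
  proj <- array(0, dim = c(d[1], d[3], length(angles)))
  for (k in seq_along(angles)) {
    R <- rotation_operator(d[1], -angles[k])
    vr <- rotate_volume(v, R)
    A <- if (is.null(att)) 1 else
      attenuation_factors(rotate_volume(att$mu, R), voxel_mm)
    w <- vr * A
    if (psf) {
      acc <- matrix(0, d[1], d[3])
      for (iy in seq_len(d[2])) {
        acc <- acc + as.matrix(apply_psf_plane(w[, iy, ], ops[[iy]]))
      }
      proj[, , k] <- acc * voxel_mm
    } else {
      proj[, , k] <- apply(w, c(1, 3), sum) * voxel_mm
    }
  }
  proj
}

#' Back projection (exact adjoint of [forward_project()])
#'
#' @param proj 3-D projection array (tangential x axial x view).
#' @param att,acq,psf As in [forward_project()].
#' @param dim_vol Volume dimensions `c(nx, ny, nz)`.
#' @param voxel_mm Voxel size in mm.
#' @return 3-D volume array.
#' @export
back_project <- function(proj, att, acq, dim_vol, voxel_mm = acq$pixel_mm,
                         psf = FALSE) {
  d <- dim_vol
  stopifnot(d[1] == d[2], dim(proj)[1] == d[1], dim(proj)[2] == d[3])
  angles <- view_angles(acq)
  stopifnot(dim(proj)[3] == length(angles))
  ops <- if (psf) psf_operators(d, acq, voxel_mm) else NULL
  out <- array(0, dim = d)
  for (k in seq_along(angles)) {
    R <- rotation_operator(d[1], -angles[k])
    A <- if (is.null(att)) NULL else
      attenuation_factors(rotate_volume(att$mu, R), voxel_mm)
    p <- proj[, , k]
    bc <- array(0, dim = d)
    if (psf) {
      for (iy in seq_len(d[2])) {
        bc[, iy, ] <- as.matrix(apply_psf_plane(p, ops[[iy]]))
      }
    } else {
      bc <- aperm(array(rep(p, d[2]), dim = c(d[1], d[3], d[2])),
                  c(1, 3, 2))
    }
    if (!is.null(A)) bc <- bc * A
    out <- out + rotate_volume_t(bc, R)
  }
  out * voxel_mm
}
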