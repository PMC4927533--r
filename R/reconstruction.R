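# OSEM reconstruction with attenuation and optional collimator PSF.

#' OSEM configuration
#'
#' @param n_subsets Number of ordered subsets (must divide the number of
#'   views); subsets interleave the view angles (view `i` belongs to subset
#'   `i mod n_subsets`).
#' @param n_iterations Number of full passes over all subsets.
#' @param psf Model the distance-dependent collimator PSF in the
#'   projectors.
#' @param postfilter_fwhm FWHM in mm of the 3-D Gaussian post-filter
#'   (0 disables it).
#' @return An `osem_config` object.
#' @export
osem_config <- function(n_subsets = 30, n_iterations = 20, psf = TRUE,
                        postfilter_fwhm = 14) {
  stopifnot(n_subsets >= 1, n_iterations >= 1, postfilter_fwhm >= 0)
  structure(list(n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations),
                 psf = isTRUE(psf), postfilter_fwhm = postfilter_fwhm),
            class = "osem_config")
}

#' Trace a uniform attenuation map from projection data
#'
#' Estimates the object support by thresholding each projection view at a
#' fraction of its maximum, back-rotating the thresholded silhouettes into
#' the volume and intersecting them across views, then fills the support
#' with a uniform attenuation coefficient.
#'
#' @param stack A [window_stack()] with 3-D (tangential x axial x view)
#'   matrices, or a plain 3-D projection array.
#' @param mu_value Uniform attenuation coefficient in mm^-1 (0.015 for
#'   Tc-99m, 0.0146 for I-123).
#' @param acq An [acquisition_spec()] providing the view angles.
#' @param threshold Silhouette threshold as a fraction of the per-view
#'   maximum.
#' @param min_view_fraction Voxels inside the silhouette in at least this
#'   fraction of views form the support.
#' @param window Window name to use when `stack` is a [window_stack()]
#'   (`NULL` sums all windows).
#' @param voxel_mm Voxel size of the output map.
#' @return An [attenuation_map()].
#' @export
trace_attenuation_map <- function(stack, mu_value = 0.015, acq,
                                  threshold = 0.05,
                                  min_view_fraction = 0.95,
                                  window = NULL, voxel_mm = acq$pixel_mm) {
  proj <- if (inherits(stack, "window_stack")) {
    if (is.null(window)) Reduce(`+`, stack$counts) else
      stack$counts[[window]]
  } else as.array(stack)
  if (length(dim(proj)) != 3L) stop("projection stack must be 3-D")
  if (all(proj <= 0)) stop("empty projections: cannot trace a contour")
  d <- dim(proj)
  angles <- view_angles(acq)
  stopifnot(d[3] == length(angles))
  dim_vol <- c(d[1], d[1], d[2])
  votes <- array(0, dim = dim_vol)
  for (k in seq_along(angles)) {
    p <- proj[, , k]
    sil <- p >= threshold * max(p)
    bc <- aperm(array(rep(sil * 1, dim_vol[2]),
                      dim = c(d[1], d[2], dim_vol[2])), c(1, 3, 2))
    R <- rotation_operator(dim_vol[1], -angles[k])
    votes <- votes + (rotate_volume_t(bc, R) >= 0.5)
  }
  support <- votes >= min_view_fraction * length(angles)
  attenuation_map(mu_value * support, voxel_mm)
}

#' Ordered-subset expectation maximization reconstruction
#'
#' Standard multiplicative OSEM with angle-interleaved subsets, attenuated
#' projectors and an optional distance-dependent PSF.  Negative input
#' counts (from scatter subtraction) are clipped to zero on entry, which is
#' the only place the pipeline clips: OSEM requires non-negative data and
#' preserves non-negativity of the iterates.  After the final iteration a
#' Gaussian post-filter of `cfg$postfilter_fwhm` mm is applied.
#'
#' @param projections 3-D projection array (tangential x axial x view), or
#'   a 2-D matrix for a single view.
#' @param att An [attenuation_map()] or `NULL`.
#' @param acq An [acquisition_spec()].
#' @param cfg An [osem_config()].
#' @param voxel_mm Reconstruction voxel size in mm (defaults to the
#'   detector pitch).
#' @return A [spect_volume()].
#' @export
osem <- function(projections, att, acq, cfg = osem_config(),
                 voxel_mm = acq$pixel_mm) {
  proj <- as.array(projections)
  if (length(dim(proj)) == 2L) dim(proj) <- c(dim(proj), 1L)
  d <- dim(proj)
  angles <- view_angles(acq)
  stopifnot(d[3] == length(angles))
  if (length(angles) %% cfg$n_subsets != 0L) {
    stop("n_subsets (", cfg$n_subsets, ") must divide the number of views (",
         length(angles), ")")
  }
  proj[proj < 0] <- 0
  dim_vol <- c(d[1], d[1], d[2])
  ops <- if (cfg$psf) psf_operators(dim_vol, acq, voxel_mm) else NULL

  # Precompute per-view rotation operators and attenuation factors.
  Rs <- lapply(angles, function(a) rotation_operator(d[1], -a))
  As <- lapply(seq_along(angles), function(k) {
    if (is.null(att)) NULL else
      attenuation_factors(rotate_volume(att$mu, Rs[[k]]), voxel_mm)
  })

  fwd_view <- function(v, k) {
    vr <- rotate_volume(v, Rs[[k]])
    if (!is.null(As[[k]])) vr <- vr * As[[k]]
    if (cfg$psf) {
      acc <- matrix(0, d[1], d[2])
      for (iy in seq_len(dim_vol[2])) {
        acc <- acc + as.matrix(apply_psf_plane(vr[, iy, ], ops[[iy]]))
      }
      acc * voxel_mm
    } else {
      colSums(aperm(vr, c(2, 1, 3))) * voxel_mm
    }
  }
  bck_view <- function(p, k) {
    if (cfg$psf) {
      bc <- array(0, dim = dim_vol)
      for (iy in seq_len(dim_vol[2])) {
        bc[, iy, ] <- as.matrix(apply_psf_plane(p, ops[[iy]]))
      }
    } else {
      bc <- aperm(array(rep(p, dim_vol[2]),
                        dim = c(d[1], d[2], dim_vol[2])), c(1, 3, 2))
    }
    if (!is.null(As[[k]])) bc <- bc * As[[k]]
    rotate_volume_t(bc, Rs[[k]]) * voxel_mm
  }

  subsets <- split(seq_along(angles),
                   (seq_along(angles) - 1L) %% cfg$n_subsets)
  # subset sensitivity images (backprojection of ones)
  sens <- lapply(subsets, function(ks) {
    s <- array(0, dim = dim_vol)
    ones <- matrix(1, d[1], d[2])
    for (k in ks) s <- s + bck_view(ones, k)
    s
  })

  x <- array(1, dim = dim_vol)
  eps <- 1e-12
  for (it in seq_len(cfg$n_iterations)) {
    for (si in seq_along(subsets)) {
      upd <- array(0, dim = dim_vol)
      for (k in subsets[[si]]) {
        fp <- fwd_view(x, k)
        ratio <- proj[, , k] / pmax(fp, eps)
        ratio[proj[, , k] == 0] <- 0
        upd <- upd + bck_view(ratio, k)
      }
      s <- sens[[si]]
      x <- x * upd / pmax(s, eps)
      x[s <= eps] <- 0
    }
  }
  vol <- spect_volume(x, voxel_mm)
  if (cfg$postfilter_fwhm > 0) {
    vol <- gaussian_postfilter(vol, cfg$postfilter_fwhm)
  }
  vol
}

#' 3-D Gaussian post-filter
#'
#' Separable Gaussian smoothing with `sigma = fwhm / 2.35482` converted to
#' voxels, applied in the frequency domain (circular convolution), so the
#' total count is preserved exactly and `fwhm = 0` is the identity.
#'
#' @param vol A [spect_volume()] or 3-D array.
#' @param fwhm Filter FWHM in mm.
#' @param voxel_mm Voxel size (taken from `vol` when it is a
#'   [spect_volume()]).
#' @return Same type as `vol`.
#' @export
gaussian_postfilter <- function(vol, fwhm = 14, voxel_mm = NULL) {
  stopifnot(fwhm >= 0)
  isvol <- inherits(vol, "spect_volume")
  v <- as_volume_array(vol)
  if (is.null(voxel_mm)) {
    voxel_mm <- if (isvol) vol$voxel_mm else
      stop("voxel_mm required for a plain array")
  }
  if (fwhm == 0) return(vol)
  sigma <- fwhm / 2.35482 / voxel_mm
  d <- dim(v)
  out <- v
  for (ax in 1:3) {
    n <- d[ax]
    freq <- fft_freq(n)
    # Fourier transform of a sampled, normalized Gaussian kernel
    H <- Re(stats::fft(gauss_kernel_circular(n, sigma)))
    out <- apply_filter_axis(out, ax, H)
  }
  if (isvol) spect_volume(out, voxel_mm) else out
}

gauss_kernel_circular <- function(n, sigma) {
  x <- fft_freq(n) * n  # positions 0, 1, ..., -1 in circular order
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

apply_filter_axis <- function(v, ax, H) {
  d <- dim(v)
  perm <- c(ax, setdiff(1:3, ax))
  vp <- aperm(v, perm)
  m <- matrix(vp, nrow = d[ax])
  m <- Re(stats::mvfft(stats::mvfft(m) * H, inverse = TRUE)) / d[ax]
  aperm(array(m, dim = d[perm]), order(perm))
}
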