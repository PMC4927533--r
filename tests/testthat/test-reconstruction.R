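test_that("forward and back projectors are exact adjoints", {
  set.seed(41)
  acq <- acquisition_spec(n_tan = 24, n_ax = 6, pixel_mm = 4,
                          n_views = 10)
  vol <- array(runif(24 * 24 * 6), c(24, 24, 6))
  att <- attenuation_map(array(0.015 * (runif(24 * 24 * 6) < 0.4),
                               c(24, 24, 6)), 4)
  y <- array(runif(24 * 6 * 10), c(24, 6, 10))
  for (psf in c(FALSE, TRUE)) {
    Fx <- forward_project(spect_volume(vol, 4), att, acq, psf = psf)
    Fty <- back_project(y, att, acq, dim_vol = c(24, 24, 6),
                        voxel_mm = 4, psf = psf)
    lhs <- sum(Fx * y); rhs <- sum(vol * Fty)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("forward projection reproduces a 1-D attenuated line integral", {
  # uniform slab: analytic front-to-back exponential weighting
  n <- 16
  acq <- acquisition_spec(n_tan = n, n_ax = 4, pixel_mm = 2, n_views = 1)
  vol <- array(1, c(n, n, 4))
  mu <- array(0.05, c(n, n, 4))
  p <- forward_project(spect_volume(vol, 2), attenuation_map(mu, 2), acq)
  # sum_y exp(-mu*dy*(n - y + 0.5)) ... voxel-centre midpoint rule
  expected <- sum(exp(-0.05 * 2 * (rev(seq_len(n)) - 0.5))) * 2
  expect_equal(p[8, 2, 1], expected, tolerance = 1e-6)
  # a single unit voxel with no attenuation projects its value everywhere
  v1 <- array(0, c(n, n, 4)); v1[8, 8, 2] <- 1
  p1 <- forward_project(spect_volume(v1, 2), NULL,
                        acquisition_spec(n_tan = n, n_ax = 4,
                                         pixel_mm = 2, n_views = 6))
  # interpolating rotation spreads a small mass fraction; totals are
  # preserved to a few percent at every angle
  for (v in 1:6) expect_equal(sum(p1[, , v]), 2, tolerance = 0.05)
})

test_that("the collimator PSF broadens with distance", {
  acq <- acquisition_spec()
  d <- c(0, 50, 100, 200)
  f <- fiveew:::psf_fwhm_mm(d, acq)
  expect_true(all(diff(f) > 0))
  expect_equal(f[1], acq$hole_mm)  # at the collimator face
  # projection of a point source spreads more when deeper
  n <- 32
  acq1 <- acquisition_spec(n_tan = n, n_ax = 8, pixel_mm = 4,
                           n_views = 1)
  spread <- sapply(c(8, 24), function(iy) {
    v <- array(0, c(n, n, 8)); v[16, iy, 4] <- 1
    p <- forward_project(spect_volume(v, 4), NULL, acq1, psf = TRUE)
    prof <- p[, 4, 1] / sum(p[, 4, 1])
    sqrt(sum(prof * (seq_len(n) - 16)^2))
  })
  expect_gt(spread[1], spread[2])  # detector is on the +y side
})

test_that("OSEM recovers a noiseless phantom and behaves predictably", {
  acq <- acquisition_spec(n_tan = 48, n_ax = 12, pixel_mm = 4,
                          n_views = 60)
  ph <- make_cylinder_phantom(120, 200, 1, 0, voxel_mm = 4, nxy = 48,
                              nz = 12)
  att <- attenuation_map(ph$mu, 4)
  truth <- ph$activity[["Tc-99m"]]
  proj <- forward_project(spect_volume(truth, 4), att, acq)
  cfg <- osem_config(n_subsets = 30, n_iterations = 20, psf = FALSE,
                     postfilter_fwhm = 0)
  rec <- osem(proj, att, acq, cfg)
  # central-region mean within 2 %
  x <- fiveew:::grid_coords(48, 4)
  m <- array(FALSE, c(48, 48, 12))
  core <- outer(x^2, x^2, `+`) <= 40^2
  for (k in 4:9) m[, , k] <- core
  expect_equal(mean(rec$values[m]), mean(truth[m]), tolerance = 0.02)
  # non-negativity of the iterates (final image suffices as witness)
  expect_true(all(rec$values >= 0))
  # homogeneity: scaling the data scales the reconstruction
  rec3 <- osem(3 * proj, att, acq, cfg)
  expect_equal(rec3$values, 3 * rec$values, tolerance = 1e-6)
  # all-zero data give a zero image
  rec0 <- osem(0 * proj, att, acq, cfg)
  expect_equal(max(abs(rec0$values)), 0)
})

test_that("OSEM reprojection mismatch decreases over iterations", {
  acq <- acquisition_spec(n_tan = 24, n_ax = 6, pixel_mm = 4,
                          n_views = 12)
  ph <- make_cylinder_phantom(60, 100, 1, 0, voxel_mm = 4, nxy = 24,
                              nz = 6)
  att <- attenuation_map(ph$mu, 4)
  proj <- forward_project(spect_volume(ph$activity[["Tc-99m"]], 4), att,
                          acq)
  mism <- sapply(c(1, 3, 6), function(nit) {
    rec <- osem(proj, att, acq,
                osem_config(n_subsets = 6, n_iterations = nit,
                            psf = FALSE, postfilter_fwhm = 0))
    rp <- forward_project(rec, att, acq)
    sum((rp - proj)^2)
  })
  expect_true(all(diff(mism) < 0))
})

test_that("Gaussian post-filter preserves counts and realizes its FWHM", {
  v <- array(0, c(41, 41, 41))
  v[21, 21, 21] <- 1
  vol <- spect_volume(v, 2)
  # fwhm = 0 is the identity
  expect_identical(gaussian_postfilter(vol, 0)$values, v)
  out <- gaussian_postfilter(vol, 14)
  expect_equal(sum(out$values), 1, tolerance = 1e-6)
  # measured FWHM of the delta response: 14 mm within half a voxel
  prof <- out$values[, 21, 21]
  half <- max(prof) / 2
  above <- range(which(prof > half))
  # sub-voxel interpolation of the crossings
  xl <- above[1] - 1 +
    (half - prof[above[1] - 1]) / (prof[above[1]] - prof[above[1] - 1])
  xr <- above[2] +
    (prof[above[2]] - half) / (prof[above[2]] - prof[above[2] + 1])
  fwhm_mm <- (xr - xl) * 2
  expect_lt(abs(fwhm_mm - 14), 1)
  # random volume: total is still preserved (circular convolution)
  set.seed(3)
  w <- array(runif(20 * 20 * 8), c(20, 20, 8))
  expect_equal(sum(gaussian_postfilter(spect_volume(w, 4), 10)$values),
               sum(w), tolerance = 1e-6)
})

test_that("attenuation map tracing recovers a cylinder support", {
  acq <- acquisition_spec(n_tan = 96, n_ax = 12, pixel_mm = 2,
                          n_views = 30)
  ph <- make_cylinder_phantom(140, 200, 1, 0, voxel_mm = 2, nxy = 96,
                              nz = 12)
  proj <- forward_project(spect_volume(ph$activity[["Tc-99m"]], 4),
                          attenuation_map(ph$mu, 4), acq)
  att <- trace_attenuation_map(proj, mu_value = 0.015, acq = acq)
  expect_equal(sort(unique(as.vector(att$mu))), c(0, 0.015))
  vol_est <- sum(att$mu > 0)
  vol_true <- sum(ph$mu > 0)
  expect_lt(abs(vol_est - vol_true) / vol_true, 0.05)
  expect_error(trace_attenuation_map(0 * proj, 0.015, acq), "empty")
})
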