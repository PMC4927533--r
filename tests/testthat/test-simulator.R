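test_that("Klein-Nishina sampler matches the analytic distribution", {
  E <- 141
  set.seed(31)
  n <- 1e5
  cth <- sample_kn(n, E)
  # chi-square against the numerically normalized differential
  # cross-section on 20 equal-width bins
  br <- seq(-1, 1, length.out = 21)
  obs <- tabulate(findInterval(cth, br, rightmost.closed = TRUE),
                  nbins = 20)
  p <- vapply(seq_len(20), function(i) {
    2 * pi * integrate(function(c0) kn_pdf(c0, E), br[i],
                       br[i + 1])$value
  }, numeric(1))
  chisq <- sum((obs - n * p)^2 / (n * p))
  expect_lt(chisq, qchisq(0.999, df = 19))
  # pdf integrates to one over the sphere
  expect_equal(2 * pi * integrate(function(c0) kn_pdf(c0, E), -1,
                                  1)$value, 1, tolerance = 1e-8)
  # Compton kinematics: forward scatter keeps the energy, backscatter at
  # 141 keV gives the classic ~90 keV
  expect_equal(compton_energy(141, 1), 141)
  expect_equal(compton_energy(141, -1), 141 / (1 + 2 * 141 / 511),
               tolerance = 1e-12)
})

test_that("cylinder phantom voxelization matches the analytic volume", {
  ph <- make_cylinder_phantom(200, 200, activity_tc = 1, activity_i = 0,
                              voxel_mm = 4)
  vox_vol <- sum(ph$activity[["Tc-99m"]] > 0) * 4^3
  expect_equal(vox_vol, pi * 100^2 * 200, tolerance = 0.01)
  # zero activity leaves the emission map empty
  expect_equal(sum(ph$activity[["I-123"]]), 0)
  # attenuation is the configured water value inside, zero outside
  expect_equal(max(ph$mu), 0.015)
  expect_equal(sort(unique(as.vector(ph$mu))), c(0, 0.015))
  expect_equal(ph$mu > 0, ph$activity[["Tc-99m"]] > 0)
})

test_that("six-compartment phantom carries the study activities", {
  ph <- make_six_compartment_phantom(voxel_mm = 4)
  act <- six_compartment_activities()
  # compartment 5 is cold for both isotopes, compartment 3 has no I-123
  expect_equal(act$tc_kbq_ml[5], 0)
  expect_equal(act$i_kbq_ml[5], 0)
  expect_equal(act$i_kbq_ml[3], 0)
  # nominal Tc:I target ratios 3:1, 0:4, 4:0, 2:2, 0:0, 1:3
  expect_equal(round(act$tc_kbq_ml / 100), c(3, 0, 4, 2, 0, 1))
  expect_equal(round(act$i_kbq_ml / 93), c(1, 4, 0, 2, 0, 3))
  for (i in 1:6) {
    sel <- ph$compartments == i
    expect_true(any(sel))
    expect_equal(unique(ph$activity[["Tc-99m"]][sel]), act$tc_kbq_ml[i])
    expect_equal(unique(ph$activity[["I-123"]][sel]), act$i_kbq_ml[i])
  }
  # all compartments sit inside the attenuating ellipse
  expect_true(all(ph$mu[ph$compartments > 0] > 0))
})

test_that("planar simulation conserves labels and is seed-deterministic", {
  acq <- small_acq()
  ph <- make_cylinder_phantom(120, 100, 5, 3, voxel_mm = 4, nxy = 40,
                              nz = 26)
  lh <- simulate_planar(ph, acq, detector_params(), n_photons = 4e4,
                        seed = 7)
  # ground truth: primary + scatter = total, everywhere, per isotope
  st_tot <- histograms_to_stack(lh, component = "total")
  st_p <- histograms_to_stack(lh, component = "primary")
  st_s <- histograms_to_stack(lh, component = "scatter")
  for (w in names(st_tot$counts)) {
    expect_equal(st_tot$counts[[w]],
                 st_p$counts[[w]] + st_s$counts[[w]])
  }
  expect_gt(sum(st_tot$counts[["Tc-main"]]), 0)
  expect_gt(sum(st_tot$counts[["I-main"]]), 0)
  # identical seeds give identical histograms; different seeds differ
  lh2 <- simulate_planar(ph, acq, detector_params(), n_photons = 4e4,
                         seed = 7)
  expect_identical(lh2$histograms, lh$histograms)
  lh3 <- simulate_planar(ph, acq, detector_params(), n_photons = 4e4,
                         seed = 8)
  expect_false(identical(lh3$histograms, lh$histograms))
})

test_that("a vacuum phantom produces no scattered counts", {
  acq <- small_acq()
  ph <- make_cylinder_phantom(120, 100, 5, 0, voxel_mm = 4, nxy = 40,
                              nz = 26, mu = 0)
  lh <- simulate_planar(ph, acq, detector_params(), n_photons = 2e4,
                        seed = 3)
  expect_equal(sum(lh$histograms[["Tc-99m"]]$scatter), 0)
  expect_gt(sum(lh$histograms[["Tc-99m"]]$primary), 0)
})

test_that("no primary Tc-99m count lies above 150 keV for a noiseless
           ideal detector", {
  acq <- small_acq()
  ph <- make_cylinder_phantom(120, 100, 5, 0, voxel_mm = 4, nxy = 40,
                              nz = 26)
  lh <- simulate_planar(ph, acq, ideal_detector_params(),
                        n_photons = 5e4, seed = 5)
  prim <- lh$histograms[["Tc-99m"]]$primary
  centers <- (lh$edges[-1] + lh$edges[-length(lh$edges)]) / 2
  expect_equal(sum(prim[centers > 150, , ]), 0)
})

test_that("scatter fraction of a Tc-only 200-mm cylinder is sane", {
  acq <- acquisition_spec(n_tan = 64, n_ax = 16, pixel_mm = 4,
                          n_views = 1)
  ph <- make_cylinder_phantom(200, 200, 1, 0, voxel_mm = 4)
  lh <- simulate_planar(ph, acq, detector_params(), n_photons = 2e5,
                        seed = 17)
  st <- histograms_to_stack(lh, component = "total")
  sc <- histograms_to_stack(lh, component = "scatter")
  sf <- sum(sc$counts[["Tc-main"]]) / sum(st$counts[["Tc-main"]])
  expect_gt(sf, 0)
  expect_lt(sf, 0.5)
})

test_that("with scatter off and an ideal detector the windows match the
           analytic attenuated projection", {
  acq <- small_acq()
  ph <- make_cylinder_phantom(120, 80, 5, 0, voxel_mm = 4, nxy = 40,
                              nz = 26)
  n <- 4e5
  lh <- simulate_planar(ph, acq, ideal_detector_params(), n_photons = n,
                        seed = 9, include_scatter = FALSE)
  detected <- sum(lh$histograms[["Tc-99m"]]$primary)
  # analytic expectation: mean over emission voxels of the transmission
  # along +y, times the fraction of emissions landing in the axial FOV
  mu <- ph$mu; act <- ph$activity[["Tc-99m"]]
  d <- dim(mu)
  trans <- array(0, d)
  for (i in seq_len(d[1])) for (k in seq_len(d[3])) {
    col <- mu[i, , k]
    trans[i, , k] <- exp(-(rev(cumsum(rev(col))) - col / 2) * 4)
  }
  z <- ((seq_len(d[3])) - (d[3] + 1) / 2) * 4
  in_fov <- abs(z) <= acq$n_ax * acq$pixel_mm / 2
  w <- act * trans
  for (k in which(!in_fov)) w[, , k] <- 0
  expected <- n * sum(w) / sum(act)
  expect_lt(abs(detected - expected), 4 * sqrt(expected))
})

test_that("dual mixing hits the requested photopeak ratios exactly", {
  acq <- small_acq()
  ph_tc <- make_cylinder_phantom(120, 80, 5, 0, voxel_mm = 4, nxy = 40,
                                 nz = 26)
  ph_i <- make_cylinder_phantom(120, 80, 0, 5, voxel_mm = 4, nxy = 40,
                                nz = 26)
  lh_tc <- simulate_planar(ph_tc, acq, detector_params(),
                           n_photons = 1e5, seed = 41)
  lh_i <- simulate_planar(ph_i, acq, detector_params(), n_photons = 1e5,
                          seed = 42)
  idx <- fiveew:::window_bin_index(lh_tc$edges, default_ws)
  for (ratio in list(c(5, 5), c(1, 9), "9:1")) {
    mx <- mix_dual(lh_tc, lh_i, ratio)
    p_tc <- sum(mx$histograms[["Tc-99m"]]$primary[idx == 2, , ])
    p_i <- sum(mx$histograms[["I-123"]]$primary[idx == 4, , ])
    rr <- if (is.character(ratio)) {
      as.numeric(strsplit(ratio, ":")[[1]])
    } else ratio
    expect_equal(p_tc / p_i, rr[1] / rr[2], tolerance = 1e-9)
    # labels conserved through mixing
    for (iso in names(mx$histograms)) {
      h <- mx$histograms[[iso]]
      expect_true(all(h$primary >= 0 & h$scatter >= 0))
    }
  }
  # a zero-photopeak input with a nonzero requested share errors
  empty <- lh_i
  empty$histograms[["I-123"]]$primary[] <- 0
  expect_error(mix_dual(lh_tc, empty, c(5, 5)), "photopeak")
})

test_that("rotating acquisition is symmetric for a central source and
           deterministic", {
  acq <- acquisition_spec(n_tan = 32, n_ax = 8, pixel_mm = 4,
                          n_views = 8)
  ph <- make_cylinder_phantom(40, 60, 10, 0, voxel_mm = 4, nxy = 32,
                              nz = 16)
  sim <- simulate_spect(ph, acq, detector_params(),
                        n_photons_per_view = 1e4, seed = 19)
  tc <- sim$stack$counts[["Tc-main"]]
  # every view peaks at the tangential centre (+- one pixel)
  for (v in seq_len(8)) {
    prof <- rowSums(tc[, , v])
    expect_lte(abs(which.max(prof) - 16.5), 2)
  }
  # uniform-ish view-to-view total counts (Poisson envelope)
  tot <- apply(tc, 3, sum)
  expect_lt(max(abs(tot - mean(tot))), 4 * sqrt(mean(tot)))
  # determinism of the whole rotation
  sim2 <- simulate_spect(ph, acq, detector_params(),
                         n_photons_per_view = 1e4, seed = 19)
  expect_identical(sim2$stack$counts, sim$stack$counts)
  # ground-truth primary stacks accompany the acquisition
  expect_true("Tc-99m" %in% names(sim$truth))
  expect_true(all(sim$truth[["Tc-99m"]]$counts[["Tc-main"]] <=
                    tc + 1e-9))
})
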