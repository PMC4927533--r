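# Reference phantom studies: planar ratio sweep and six-compartment
# recovery.  These reproduce, at a reduced problem size, the two
# quantitative evaluations the correction method is judged by: percentage
# error against ground-truth primary counts across Tc:I photopeak ratios,
# and linearity/residual-scatter of activity recovery after
# reconstruction and cross-calibration.

#' Planar dual-isotope ratio study
#'
#' Simulates single-isotope planar acquisitions of the 200-mm uniform
#' cylinder, mixes them at a series of Tc:I photopeak count ratios and
#' evaluates the percentage error between corrected and ground-truth
#' primary counts for no correction, FiveEW-woDR and FiveEW per isotope.
#'
#' @param n_photons_tc,n_photons_i Emission samples per single-isotope
#'   run (defaults give over 1e6 photopeak counts each).
#' @param seed Master seed.
#' @param ratios List/matrix of Tc:I ratios; default 1:9 ... 9:1.
#' @param acq,det Acquisition and detector models.
#' @param filt Scatter filter; defaults to the physically scaled cutoff
#'   for the acquisition pitch.
#' @param response_samples Samples for the primary detector responses.
#' @return data.frame with one row per ratio: percentage errors per
#'   method and isotope, plus the Poisson-propagated Monte Carlo standard
#'   error of the corrected-count totals (columns `se_tc`, `se_i`, in
#'   percent of the primary counts).  Attributes carry the responses and
#'   photopeak counts.
#' @export
ratio_study <- function(n_photons_tc = 1e7, n_photons_i = 1.4e7,
                        seed = 1,
                        ratios = lapply(1:9, function(k) c(k, 10 - k)),
                        acq = acquisition_spec(n_tan = 96, n_ax = 32,
                                               pixel_mm = 2.8,
                                               n_views = 1),
                        det = detector_params(),
                        filt = scatter_filter_spec(
                          cutoff = scaled_filter_cutoff(acq$pixel_mm)),
                        response_samples = 2e6) {
  ws <- make_default_windows()
  ph_tc <- make_cylinder_phantom(200, 200, 1, 0, voxel_mm = 4)
  ph_i <- make_cylinder_phantom(200, 200, 0, 1, voxel_mm = 4)
  lh_tc <- simulate_planar(ph_tc, acq, det, n_photons = n_photons_tc,
                           seed = derive_seed(seed, 11L))
  lh_i <- simulate_planar(ph_i, acq, det, n_photons = n_photons_i,
                          seed = derive_seed(seed, 12L))
  resp_tc <- isotope_response("Tc-99m", det,
                              n_samples = response_samples,
                              seed = derive_seed(seed, 21L))
  resp_i <- isotope_response("I-123", det, n_samples = response_samples,
                             seed = derive_seed(seed, 22L))
  co_tc <- tew_coefficients(ws[["Tc-lower"]], ws[["Tc-main"]],
                            ws[["intermediate"]])
  co_i <- tew_coefficients(ws[["intermediate"]], ws[["I-main"]],
                           ws[["I-upper"]])

  rows <- lapply(ratios, function(rt) {
    mx <- mix_dual(lh_tc, lh_i, rt, ws)
    stack <- histograms_to_stack(mx, ws)
    P_tc <- sum(histograms_to_stack(mx, ws, "primary",
                                    "Tc-99m")$counts[["Tc-main"]])
    P_i <- sum(histograms_to_stack(mx, ws, "primary",
                                   "I-123")$counts[["I-main"]])
    dr <- five_ew(stack, resp_tc, resp_i, filt, use_dr = TRUE, ws = ws)
    wo <- five_ew(stack, resp_tc, resp_i, filt, use_dr = FALSE, ws = ws)
    E <- stack$counts
    # Poisson propagation of the corrected-count totals through the
    # closed-form correction (filtering preserves totals)
    se_branch <- function(co, r, N_L, N_M, N_U) {
      aM <- 1 / (1 - co$alpha * r)
      aL <- co$alpha / (1 - co$alpha * r)
      aU <- co$beta / (1 - co$alpha * r)
      sqrt(aM^2 * N_M + aL^2 * N_L + aU^2 * N_U)
    }
    se_i <- 100 * se_branch(co_i, resp_i$r, sum(E[["intermediate"]]),
                            sum(E[["I-main"]]),
                            sum(E[["I-upper"]])) / P_i
    se_tc <- 100 * se_branch(co_tc, resp_tc$r, sum(E[["Tc-lower"]]),
                             sum(E[["Tc-main"]]),
                             sum(E[["intermediate"]])) / P_tc
    data.frame(
      ratio_tc = rt[1], ratio_i = rt[2],
      err_none_tc = percentage_error(sum(E[["Tc-main"]]), P_tc),
      err_wodr_tc = percentage_error(sum(wo$tc_primary), P_tc),
      err_dr_tc = percentage_error(sum(dr$tc_primary), P_tc),
      err_none_i = percentage_error(sum(E[["I-main"]]), P_i),
      err_wodr_i = percentage_error(sum(wo$i_primary), P_i),
      err_dr_i = percentage_error(sum(dr$i_primary), P_i),
      se_tc = se_tc, se_i = se_i,
      photopeak_tc = P_tc, photopeak_i = P_i
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "responses") <- list(tc = resp_tc, i = resp_i)
  attr(out, "histograms") <- list(tc = lh_tc, i = lh_i)
  attr(out, "filter") <- filt
  out
}

#' Six-compartment activity recovery study
#'
#' Full chain at a reduced grid: rotating acquisitions of the uniform
#' cylinder (cross-calibration) and the six-compartment phantom, FiveEW
#' correction, OSEM reconstruction with traced uniform attenuation, ROI
#' analysis, and the linearity / residual-scatter metrics per isotope.
#'
#' @param seed Master seed.
#' @param sensitivity_per_mbq_view Emission samples per MBq of total
#'   phantom activity per view.  Counts must scale with activity for
#'   cross-calibration factors to transfer between phantoms, so both
#'   acquisitions share this single count-rate constant; the default
#'   gives roughly 9e5 emissions per view for the six-compartment
#'   phantom, enough that Monte Carlo noise is well below the
#'   residual-scatter levels of interest.
#' @param acq Acquisition geometry (64 x 16 pixels at 4 mm pitch, 60
#'   views by default).
#' @param det Detector model.
#' @param method Correction method passed to [correct_stack()].
#' @param osem_cfg OSEM configuration.
#' @param response_samples Samples for the detector responses.
#' @param cyl_activity_tc,cyl_activity_i Uniform-cylinder concentrations
#'   (kBq/ml) used for cross-calibration.
#' @return A list with per-isotope results (`estimated`, `injected`,
#'   `r_squared`, `slope`, `rs_percent`), the calibration factors, the
#'   percentage the Tc-only compartment contributes to the hot-compartment
#'   mean of the I-123 image (`tc_in_i_percent`), and the ROI report.
#' @export
phantom_recovery_study <- function(seed = 1,
                                   sensitivity_per_mbq_view = 4000,
                                   acq = acquisition_spec(
                                     n_tan = 64, n_ax = 16, pixel_mm = 4,
                                     n_views = 60),
                                   det = detector_params(),
                                   method = "fiveew",
                                   osem_cfg = osem_config(),
                                   response_samples = 2e6,
                                   cyl_activity_tc = 17.8,
                                   cyl_activity_i = 12.3) {
  ws <- make_default_windows()
  filt <- scatter_filter_spec(cutoff = scaled_filter_cutoff(acq$pixel_mm))
  resp_tc <- isotope_response("Tc-99m", det,
                              n_samples = response_samples,
                              seed = derive_seed(seed, 31L))
  resp_i <- isotope_response("I-123", det, n_samples = response_samples,
                             seed = derive_seed(seed, 32L))
  dim_vol <- c(acq$n_tan, acq$n_tan, acq$n_ax)
  mu_of <- c("Tc-99m" = 0.015, "I-123" = 0.0146)

  reconstruct_iso <- function(sim, corrected, iso) {
    att <- trace_attenuation_map(sim$stack, mu_value = mu_of[[iso]],
                                 acq = acq)
    osem(corrected[[iso]], att, acq, osem_cfg)
  }

  ## cylinder: cross-calibration factors --------------------------------
  cyl <- make_cylinder_phantom(200, 200, cyl_activity_tc, cyl_activity_i,
                               voxel_mm = acq$pixel_mm,
                               nxy = acq$n_tan)
  sim_c <- simulate_spect(cyl, acq, det,
                          n_photons_per_view = round(
                            sensitivity_per_mbq_view *
                              sum(total_activity_mbq(cyl))),
                          seed = derive_seed(seed, 41L))
  cor_c <- correct_stack(sim_c$stack, method, resp_tc, resp_i, filt, ws)
  rois_u <- uniform_phantom_rois(dim_vol, acq$pixel_mm,
                                 roi_length_mm = min(
                                   100, 0.6 * acq$n_ax * acq$pixel_mm))
  true_act <- c("Tc-99m" = cyl_activity_tc, "I-123" = cyl_activity_i)
  factors <- sapply(c("Tc-99m", "I-123"), function(iso) {
    rec <- reconstruct_iso(sim_c, cor_c, iso)
    cross_calibrate(mean(roi_stats(rec, rois_u)$mean), true_act[[iso]])
  })

  ## six-compartment phantom ---------------------------------------------
  six <- make_six_compartment_phantom(voxel_mm = acq$pixel_mm,
                                      nxy = acq$n_tan)
  sim_s <- simulate_spect(six, acq, det,
                          n_photons_per_view = round(
                            sensitivity_per_mbq_view *
                              sum(total_activity_mbq(six))),
                          seed = derive_seed(seed, 42L))
  cor_s <- correct_stack(sim_s$stack, method, resp_tc, resp_i, filt, ws)
  rois_s <- six_compartment_rois(dim_vol, acq$pixel_mm, phantom = six)
  act <- six_compartment_activities()

  results <- list()
  report <- NULL
  for (iso in c("Tc-99m", "I-123")) {
    rec <- reconstruct_iso(sim_s, cor_s, iso)
    st <- roi_stats(rec, rois_s)
    st$isotope <- iso
    report <- rbind(report, st)
    est <- factors[[iso]] * tapply(st$mean, st$compartment, mean)
    inj <- if (iso == "Tc-99m") act$tc_kbq_ml else act$i_kbq_ml
    hot <- inj > 0
    lin <- activity_linearity(est[hot], inj[hot])
    results[[iso]] <- list(
      estimated = est, injected = inj,
      r_squared = lin$r_squared, slope = lin$slope,
      pd_percent = percentage_error(est[hot], inj[hot]),
      rs_percent = residual_scatter(est[!hot], est[hot])
    )
  }
  # contamination of the I-123 image by the Tc-only compartment (3)
  est_i <- results[["I-123"]]$estimated
  hot_i <- act$i_kbq_ml > 0
  tc_in_i <- 100 * est_i[3] / mean(est_i[hot_i])

  list(results = results, factors = factors,
       tc_in_i_percent = unname(tc_in_i), report = report,
       responses = list(tc = resp_tc, i = resp_i),
       acq = acq, seed = seed)
}
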