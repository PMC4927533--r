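# Energy response of a pixelated CdTe-like detector.
#
# Primary gamma rays deposit a pulse height E * CCE(z) / CCE(z*), where
# CCE is the Hecht charge-collection efficiency at interaction depth z and
# z* is the depth of maximum collection (the energy scale is calibrated so
# the photopeak sits at the nominal line energy).  Incomplete hole
# collection produces the characteristic low-energy tail ("photopeak
# spillover") of solid-state detectors; Fano-limited carrier statistics and
# electronic noise add a Gaussian spread.

#' Detector model parameters
#'
#' @param thickness Crystal thickness d in mm.
#' @param lambda_e,lambda_h Effective drift lengths (mobility-lifetime-field
#'   products) of electrons and holes, in mm.  Small `lambda_h` produces a
#'   pronounced low-energy tail.
#' @param fano Fano factor (unitless, 0 < F < 1).
#' @param pair_energy Energy per electron-hole pair in keV (CdTe: 4.43 eV).
#' @param noise_sigma Electronic-noise standard deviation in keV.
#' @param depth_mean,depth_sigma Mean and SD (mm) of the Gaussian
#'   interaction-depth model, truncated to `[0, thickness]`; depth is
#'   measured from the photon-entry (cathode) face.  Defaults place most
#'   interactions near the entry face.
#' @return A `detector_params` object.
#' @details The defaults were calibrated in-package so that the simulated
#'   Tc-99m photopeak has a 6.6 % FWHM at 141 keV with a visible
#'   low-energy tail, while leaving the region above 150 keV (the I-123
#'   lower sub-window) essentially free of Tc-99m counts, matching the
#'   design intent of the five-window scheme.  All parameters are
#'   user-overridable.
#' @export
detector_params <- function(thickness = 5,
                            lambda_e = 100,
                            lambda_h = 5,
                            fano = 0.11,
                            pair_energy = 0.00443,
                            noise_sigma = 2.25,
                            depth_mean = thickness / 4,
                            depth_sigma = thickness / 4) {
  stopifnot(thickness > 0, lambda_e > 0, lambda_h > 0,
            fano > 0, fano < 1, pair_energy > 0, noise_sigma >= 0,
            depth_mean >= 0, depth_mean <= thickness, depth_sigma >= 0)
  structure(list(thickness = thickness, lambda_e = lambda_e,
                 lambda_h = lambda_h, fano = fano,
                 pair_energy = pair_energy, noise_sigma = noise_sigma,
                 depth_mean = depth_mean, depth_sigma = depth_sigma),
            class = "detector_params")
}

#' An idealized detector (unit charge collection, no noise)
#'
#' Convenience parameter set whose response to a monoenergetic line is a
#' delta spectrum: drift lengths far larger than the crystal, zero
#' electronic noise and a negligible Fano contribution.
#' @export
ideal_detector_params <- function() {
  detector_params(thickness = 5, lambda_e = 1e9, lambda_h = 1e9,
                  fano = 1e-9, pair_energy = 0.00443, noise_sigma = 0)
}

#' Hecht charge-collection efficiency
#'
#' \deqn{CCE(z) = \frac{\lambda_e}{d}\left(1 - e^{-(d-z)/\lambda_e}\right)
#'             + \frac{\lambda_h}{d}\left(1 - e^{-z/\lambda_h}\right)}
#' with `z` the interaction depth measured from the photon-entry (cathode)
#' face of a planar detector of thickness `d`.
#'
#' @param z Interaction depth(s) in mm, within `[0, thickness]`.
#' @param p A [detector_params()] object.
#' @return Charge-collection efficiency in `[0, 1]`, vectorized over `z`.
#' @export
hecht_cce <- function(z, p) {
  stopifnot(inherits(p, "detector_params"))
  if (any(z < 0 | z > p$thickness)) {
    stop("interaction depth outside [0, ", p$thickness, "] mm")
  }
  d <- p$thickness
  (p$lambda_e / d) * (1 - exp(-(d - z) / p$lambda_e)) +
    (p$lambda_h / d) * (1 - exp(-z / p$lambda_h))
}

# Depth of maximum charge collection: (d - z)/lambda_e = z/lambda_h.
cce_peak_depth <- function(p) {
  z <- p$thickness * p$lambda_h / (p$lambda_e + p$lambda_h)
  min(max(z, 0), p$thickness)
}

# Reference CCE used for energy-scale calibration (photopeak at nominal E).
cce_reference <- function(p) hecht_cce(cce_peak_depth(p), p)

# Truncated-Gaussian interaction depths via inverse-CDF sampling.
sample_depth <- function(n, p) {
  if (p$depth_sigma <= 0) return(rep(p$depth_mean, n))
  plo <- stats::pnorm(0, p$depth_mean, p$depth_sigma)
  phi <- stats::pnorm(p$thickness, p$depth_mean, p$depth_sigma)
  u <- stats::runif(n, plo, phi)
  z <- stats::qnorm(u, p$depth_mean, p$depth_sigma)
  pmin(pmax(z, 0), p$thickness)
}

#' Simulate deposited pulse heights for incident photon energies
#'
#' For each incident energy: sample an interaction depth, scale by the
#' calibrated Hecht efficiency, and add Gaussian noise with variance
#' `fano * pair_energy * E + noise_sigma^2` (keV^2).
#'
#' @param energies Incident photon energies in keV.
#' @param p A [detector_params()] object.
#' @return Deposited pulse heights in keV (same length as `energies`).
#' @export
deposit_energies <- function(energies, p) {
  n <- length(energies)
  if (n == 0L) return(numeric(0))
  z <- sample_depth(n, p)
  pulse <- energies * hecht_cce(z, p) / cce_reference(p)
  sd <- sqrt(p$fano * p$pair_energy * energies + p$noise_sigma^2)
  if (any(sd > 0)) pulse <- pulse + stats::rnorm(n, 0, sd)
  pulse
}

#' Known emission lines of the supported isotopes
#'
#' @param isotope `"Tc-99m"` or `"I-123"`.
#' @return A list with `energies` (keV) and `intensities` (photons per
#'   decay).  The weak 529-keV line of I-123 is included because its
#'   down-scatter is the contamination the I-upper window is designed to
#'   estimate.
#' @export
emission_lines <- function(isotope) {
  switch(isotope,
    "Tc-99m" = list(energies = 140.5, intensities = 0.89),
    "I-123"  = list(energies = c(159.0, 529.0),
                    intensities = c(0.83, 0.014)),
    stop("unknown isotope '", isotope, "'")
  )
}

#' Monte Carlo primary-gamma detector response
#'
#' Samples `n_samples` primary photons from the given emission lines, passes
#' them through the detector model and returns the normalized energy
#' spectrum together with per-window sensitivities `S` and the spillover
#' ratio `r` used by the detector-response-corrected scatter estimators.
#'
#' @param line_energies Emission energies in keV.
#' @param intensities Branching ratios (photons/decay), same length.
#' @param p A [detector_params()] object.
#' @param n_samples Number of sampled photons.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   response.
#' @param isotope Isotope tag stored on the response; selects which window
#'   pair defines `r` (`Tc-lower`/`Tc-main` for Tc-99m, `intermediate`/
#'   `I-main` for I-123).
#' @param ws Window set used for the sensitivities.
#' @param edges Histogram bin edges in keV.
#' @return A `detector_response` object with fields `spectrum` (sums to 1),
#'   `energies` (bin centres), `S` (named sensitivities) and `r`.
#' @export
apply_energy_response <- function(line_energies, intensities, p,
                                  n_samples = 2e6, seed = 1,
                                  isotope = "Tc-99m",
                                  ws = make_default_windows(),
                                  edges = default_energy_edges()) {
  stopifnot(length(line_energies) == length(intensities),
            all(intensities >= 0), n_samples >= 1)
  if (sum(intensities) <= 0) stop("total line intensity must be positive")
  set.seed(as.integer(seed))
  line <- sample.int(length(line_energies), n_samples, replace = TRUE,
                     prob = intensities)
  pulse <- deposit_energies(line_energies[line], p)
  counts <- bin_energies(pulse, edges)
  response_from_spectrum(counts, edges, isotope = isotope, ws = ws,
                         params = p, seed = seed)
}

# Histogram energies onto fixed bin edges; out-of-range events are dropped.
bin_energies <- function(e, edges) {
  nb <- length(edges) - 1L
  idx <- findInterval(e, edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1L & idx <= nb]
  tabulate(idx, nbins = nb)
}

#' Build a detector response from a measured or simulated spectrum
#'
#' @param counts Counts per energy bin.
#' @param edges Bin edges in keV.
#' @param isotope Isotope tag (see [apply_energy_response()]).
#' @param ws Window set for sensitivities.
#' @param params,seed Optional provenance stored on the object.
#' @return A `detector_response` object.
#' @export
response_from_spectrum <- function(counts, edges, isotope,
                                   ws = make_default_windows(),
                                   params = NULL, seed = NULL) {
  total <- sum(counts)
  if (total <= 0) stop("empty spectrum")
  spectrum <- counts / total
  idx <- window_bin_index(edges, ws)
  S <- vapply(seq_along(ws), function(i) sum(spectrum[idx == i]),
              numeric(1))
  names(S) <- names(ws)
  pair <- spillover_window_pair(isotope)
  r <- if (S[[pair[2]]] > 0) S[[pair[1]]] / S[[pair[2]]] else 0
  structure(list(isotope = isotope,
                 energies = (edges[-1] + edges[-length(edges)]) / 2,
                 edges = edges, spectrum = spectrum, S = S, r = r,
                 params = params, seed = seed),
            class = "detector_response")
}

# (lower sub-window, main window) pair whose sensitivity ratio defines r.
spillover_window_pair <- function(isotope) {
  switch(isotope,
         "Tc-99m" = c("Tc-lower", "Tc-main"),
         "I-123" = c("intermediate", "I-main"),
         stop("unknown isotope '", isotope, "'"))
}

#' @export
print.detector_response <- function(x, ...) {
  cat(sprintf("<detector_response> %s  (r = %.4f)\n", x$isotope, x$r))
  cat("  S:", paste(sprintf("%s=%.4f", names(x$S), x$S), collapse = ", "),
      "\n")
  invisible(x)
}

#' Default primary response for one isotope
#'
#' Convenience wrapper around [apply_energy_response()] with the isotope's
#' emission lines.
#' @inheritParams apply_energy_response
#' @export
isotope_response <- function(isotope, p = detector_params(),
                             n_samples = 2e6, seed = 1,
                             ws = make_default_windows(),
                             edges = default_energy_edges()) {
  lines <- emission_lines(isotope)
  apply_energy_response(lines$energies, lines$intensities, p,
                        n_samples = n_samples, seed = seed,
                        isotope = isotope, ws = ws, edges = edges)
}

#' Photopeak energy resolution of a response spectrum
#'
#' Measures the full width at half maximum of the photopeak as a percentage
#' of the photopeak energy.  The peak region is the contiguous run of bins
#' above half of the peak maximum around the bin nearest `photopeak`; the
#' half-maximum crossing points are located by linear interpolation between
#' bins, so the result is not quantized to the bin width.
#'
#' @param response A `detector_response` (or list with `energies` and
#'   `spectrum`).
#' @param photopeak Photopeak energy in keV.
#' @return FWHM / photopeak * 100 (percent).
#' @export
fwhm_percent <- function(response, photopeak) {
  e <- response$energies
  y <- response$spectrum
  if (photopeak < min(e) || photopeak > max(e)) {
    stop("photopeak outside spectrum range")
  }
  # peak bin: maximum within +-15 % of the nominal photopeak
  near <- which(abs(e - photopeak) <= 0.15 * photopeak)
  if (!length(near) || all(y[near] <= 0)) stop("no identifiable peak")
  ipk <- near[which.max(y[near])]
  half <- y[ipk] / 2
  # walk outwards while above half-max
  lo <- ipk
  while (lo > 1L && y[lo - 1L] > half) lo <- lo - 1L
  hi <- ipk
  while (hi < length(y) && y[hi + 1L] > half) hi <- hi + 1L
  # sub-bin interpolation of the crossing points
  left <- if (lo == 1L) e[lo] else {
    e[lo - 1L] + (half - y[lo - 1L]) / (y[lo] - y[lo - 1L]) *
      (e[lo] - e[lo - 1L])
  }
  right <- if (hi == length(y)) e[hi] else {
    e[hi] + (y[hi] - half) / (y[hi] - y[hi + 1L]) * (e[hi + 1L] - e[hi])
  }
  (right - left) / photopeak * 100
}
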