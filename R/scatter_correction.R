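# TEW / TEWDR / FiveEW scatter and crosstalk correction.
#
# TEW estimates the scatter under a main window from two flanking
# sub-windows.  On pixelated solid-state detectors the sub-windows also
# contain primary counts (photopeak spillover), which makes plain TEW
# overcorrect.  TEWDR removes the estimated primary fraction from the lower
# sub-window using the spillover ratio r measured on a scatter-free
# detector response before forming the scatter estimate.  FiveEW applies
# TEWDR per isotope on a five-window acquisition, after subtracting the
# I-123 -> Tc crosstalk estimated from the raw I-main window.

#' Scatter-smoothing filter specification
#'
#' Low-pass Butterworth filter applied to the estimated scatter term to
#' reduce its statistical fluctuation (the primary term is left untouched).
#'
#' @param order Filter order (>= 1).
#' @param cutoff Cut-off frequency in cycles/pixel, in (0, 0.5).
#' @param enabled Logical; when `FALSE` the estimators use the raw scatter
#'   term.
#' @param pad Boundary handling for the frequency-domain filter:
#'   `"symmetric"` (mirror padding, suppresses edge ringing) or `"none"`
#'   (circular convolution).
#' @return A `scatter_filter_spec` object.
#' @export
scatter_filter_spec <- function(order = 8, cutoff = 0.056, enabled = TRUE,
                                pad = c("symmetric", "none")) {
  stopifnot(order >= 1, cutoff > 0, cutoff < 0.5)
  pad <- match.arg(pad)
  structure(list(order = order, cutoff = cutoff, enabled = isTRUE(enabled),
                 pad = pad),
            class = "scatter_filter_spec")
}

#' Pixel-pitch-matched scatter filter cutoff
#'
#' The scatter filter cutoff is specified in cycles/pixel for the
#' reference detector pitch (1.4 mm).  When working on a coarser grid the
#' physically equivalent cutoff (same cycles/mm) is
#' `base_cutoff * pixel_mm / base_pixel_mm`, capped just below the Nyquist
#' limit.
#'
#' @param pixel_mm Pixel pitch of the working grid in mm.
#' @param base_cutoff Reference cutoff in cycles/pixel.
#' @param base_pixel_mm Reference pixel pitch in mm.
#' @return Cutoff in cycles/pixel for the working grid.
#' @export
scaled_filter_cutoff <- function(pixel_mm, base_cutoff = 0.056,
                                 base_pixel_mm = 1.4) {
  min(base_cutoff * pixel_mm / base_pixel_mm, 0.45)
}

#' Butterworth low-pass gain
#'
#' \deqn{|H(\nu)| = \left[1 + (\nu/\nu_c)^{2n}\right]^{-1/2}}
#' DC gain is 1 and the gain at the cut-off frequency is exactly
#' \eqn{1/\sqrt{2}}.
#'
#' @param nu Radial spatial frequency in cycles/pixel (vectorized).
#' @param order Filter order n.
#' @param cutoff Cut-off frequency \eqn{\nu_c} in cycles/pixel.
#' @return Gain values in (0, 1].
#' @export
butterworth_gain <- function(nu, order = 8, cutoff = 0.056) {
  1 / sqrt(1 + (nu / cutoff)^(2 * order))
}

# 2-D frequency-domain Butterworth smoothing of one image.
butterworth_smooth_2d <- function(img, spec) {
  img <- as.matrix(img)
  n1 <- nrow(img); n2 <- ncol(img)
  if (spec$pad == "symmetric") {
    # mirror the image to twice the size; circular filtering of the
    # mirrored image is equivalent to symmetric-boundary filtering
    img_p <- rbind(img, img[n1:1, , drop = FALSE])
    img_p <- cbind(img_p, img_p[, n2:1, drop = FALSE])
  } else {
    img_p <- img
  }
  m1 <- nrow(img_p); m2 <- ncol(img_p)
  f1 <- fft_freq(m1); f2 <- fft_freq(m2)
  nu <- sqrt(outer(f1^2, f2^2, `+`))
  H <- butterworth_gain(nu, spec$order, spec$cutoff)
  sm <- Re(stats::fft(stats::fft(img_p) * H, inverse = TRUE)) / (m1 * m2)
  sm[seq_len(n1), seq_len(n2), drop = FALSE]
}

# DFT sample frequencies in cycles/sample.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Smooth an image with the scatter Butterworth filter
#'
#' Applies the radially symmetric Butterworth low-pass in the frequency
#' domain.  For a 3-D stack the filter is applied per view (2-D, in the
#' tangential x axial plane).  The mean value is preserved (DC gain 1).
#'
#' @param image 2-D matrix or 3-D array (tangential x axial x view).
#' @param spec A [scatter_filter_spec()].
#' @return Smoothed array of the same shape.
#' @export
butterworth_smooth <- function(image, spec = scatter_filter_spec()) {
  if (!all(is.finite(image))) stop("image must be finite")
  d <- dim(image)
  if (is.null(d) || length(d) == 2L) {
    return(butterworth_smooth_2d(image, spec))
  }
  if (length(d) == 3L) {
    out <- image
    for (v in seq_len(d[3])) {
      out[, , v] <- butterworth_smooth_2d(image[, , v], spec)
    }
    return(out)
  }
  stop("image must be 2-D or 3-D")
}

check_same_shape <- function(...) {
  mats <- list(...)
  d <- lapply(mats, function(m) dim(as.array(m)))
  if (!all(vapply(d, identical, logical(1), d[[1]]))) {
    stop("window matrices must share one shape")
  }
  invisible(TRUE)
}

#' Triple-energy-window scatter correction
#'
#' \deqn{TEW(E_L, E_M, E_U) = E_M - (\alpha E_L + \beta E_U)}
#' applied elementwise.  Negative results are preserved (clipping, when
#' needed, is deferred to reconstruction).
#'
#' @param E_L,E_M,E_U Count matrices (any common shape).
#' @param coeffs A [tew_coefficients()] object.
#' @return Scatter-corrected main-window matrix.
#' @export
tew <- function(E_L, E_M, E_U, coeffs) {
  stopifnot(inherits(coeffs, "tew_coefficients"))
  check_same_shape(E_L, E_M, E_U)
  E_M - (coeffs$alpha * E_L + coeffs$beta * E_U)
}

#' Detector-response-corrected TEW (TEWDR)
#'
#' Solves the spillover fixed point `P_L = r * TEW(E_L - P_L, E_M, E_U)` in
#' closed form and subtracts the resulting scatter estimate
#' \deqn{\hat S = \alpha\,\frac{E_L - r E_M + \beta r E_U}{1 - \alpha r}
#'              + \beta E_U}
#' (optionally Butterworth-smoothed) from the main window.  With `r = 0`
#' and the filter disabled this reduces exactly to [tew()]; with the filter
#' disabled the result also equals `TEW(E_L, E_M, E_U) / (1 - alpha * r)`.
#'
#' @inheritParams tew
#' @param r Spillover ratio (lower sub-window / main window sensitivity of
#'   the primary detector response); requires `alpha * r != 1`.
#' @param filt Optional [scatter_filter_spec()]; `NULL` disables smoothing.
#' @return Scatter-corrected main-window matrix.
#' @export
tewdr <- function(E_L, E_M, E_U, coeffs, r, filt = NULL) {
  stopifnot(inherits(coeffs, "tew_coefficients"), r >= 0)
  check_same_shape(E_L, E_M, E_U)
  a <- coeffs$alpha; b <- coeffs$beta
  if (abs(1 - a * r) < 1e-12) {
    stop("singular configuration: alpha * r = 1")
  }
  scatter <- a * (E_L - r * E_M + b * r * E_U) / (1 - a * r) + b * E_U
  if (!is.null(filt) && inherits(filt, "scatter_filter_spec") &&
      filt$enabled) {
    scatter <- butterworth_smooth(scatter, filt)
  }
  E_M - scatter
}

#' I-123 -> Tc crosstalk estimate
#'
#' Estimates the contamination of the Tc-related windows by I-123 as
#' `CI_x = (S_x / S_I-main) * E_I-main`, using the *raw* I-main counts
#' (primary plus scatter): crosstalk arises from limited energy resolution,
#' incomplete charge collection and down-scatter of higher photopeaks, and
#' subtracting on the raw window also removes object scatter originating
#' from I-123 that the Tc-window TEW estimate cannot attribute.
#'
#' @param E_I_main Raw I-main count matrix.
#' @param resp_I `detector_response` for I-123 (provides the sensitivities).
#' @param windows Tc-related windows to estimate, by name.
#' @return A `crosstalk_map`: named list of matrices `CI`.
#' @export
crosstalk <- function(E_I_main, resp_I,
                      windows = c("Tc-lower", "Tc-main", "intermediate")) {
  stopifnot(inherits(resp_I, "detector_response"))
  S <- resp_I$S
  if (!all(c(windows, "I-main") %in% names(S))) {
    stop("response lacks sensitivities for required windows")
  }
  if (S[["I-main"]] <= 0) stop("S_I-main must be positive")
  CI <- lapply(windows, function(w) (S[[w]] / S[["I-main"]]) * E_I_main)
  names(CI) <- windows
  structure(list(CI = CI, ratios = S[windows] / S[["I-main"]]),
            class = "crosstalk_map")
}

#' FiveEW scatter and crosstalk correction
#'
#' Pixel-by-pixel correction of a five-window acquisition:
#' \itemize{
#'   \item I-123 branch: TEWDR on (intermediate, I-main, I-upper) with the
#'     I-123 coefficients and spillover ratio.  No Tc-related window
#'     enters, so the I-123 image is independent of the Tc-99m activity.
#'   \item Tc-99m branch: the I-123 crosstalk [crosstalk()] (computed from
#'     the raw I-main window) is subtracted from Tc-lower, Tc-main and
#'     intermediate, then TEWDR is applied on the corrected triple with the
#'     Tc-99m coefficients and spillover ratio.
#' }
#' With `use_dr = FALSE` both branches use plain [tew()] instead of TEWDR
#' (the "FiveEW-woDR" variant).
#'
#' @param stack A [window_stack()] containing all five windows.
#' @param resp_tc,resp_i Primary detector responses for Tc-99m and I-123.
#' @param filt Optional [scatter_filter_spec()].
#' @param use_dr Use the detector-response correction (default `TRUE`).
#' @param ws Window definitions (for the TEW coefficients).
#' @param clip_subwindows Clip crosstalk-subtracted sub-windows at zero
#'   before the Tc-branch TEW step (default `FALSE`, which keeps the whole
#'   chain linear).
#' @return A `correction_result` with `tc_primary`, `i_primary`, the
#'   per-branch scatter/crosstalk estimates and the coefficients used.
#' @export
five_ew <- function(stack, resp_tc, resp_i, filt = NULL, use_dr = TRUE,
                    ws = make_default_windows(), clip_subwindows = FALSE) {
  stopifnot(inherits(stack, "window_stack"))
  missing <- setdiff(FIVEEW_WINDOW_NAMES, names(stack$counts))
  if (length(missing)) {
    stop("stack is missing window(s): ", paste(missing, collapse = ", "))
  }
  E <- stack$counts
  co_tc <- tew_coefficients(ws[["Tc-lower"]], ws[["Tc-main"]],
                            ws[["intermediate"]])
  co_i <- tew_coefficients(ws[["intermediate"]], ws[["I-main"]],
                           ws[["I-upper"]])
  r_tc <- if (use_dr) resp_tc$r else 0
  r_i <- if (use_dr) resp_i$r else 0

  sc <- function(L, M, U, co, r) {
    if (use_dr) tewdr(L, M, U, co, r, filt) else tewdr(L, M, U, co, 0, filt)
  }
  i_primary <- sc(E[["intermediate"]], E[["I-main"]], E[["I-upper"]],
                  co_i, r_i)

  xt <- crosstalk(E[["I-main"]], resp_i)
  sub <- function(w) {
    m <- E[[w]] - xt$CI[[w]]
    if (clip_subwindows) m[m < 0] <- 0
    m
  }
  tc_primary <- sc(sub("Tc-lower"), sub("Tc-main"), sub("intermediate"),
                   co_tc, r_tc)

  structure(list(
    tc_primary = tc_primary,
    i_primary = i_primary,
    crosstalk = xt,
    diagnostics = list(
      coeffs_tc = co_tc, coeffs_i = co_i,
      r_tc = r_tc, r_i = r_i, use_dr = use_dr,
      filter = filt
    ),
    pixel_mm = stack$pixel_mm,
    view_angles = stack$view_angles
  ), class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<correction_result> %s (r_Tc = %.4f, r_I = %.4f)\n",
              if (d$use_dr) "FiveEW" else "FiveEW-woDR", d$r_tc, d$r_i))
  cat(sprintf("  total Tc primary: %.4g   total I primary: %.4g\n",
              sum(x$tc_primary), sum(x$i_primary)))
  invisible(x)
}

#' Iterative spillover correction for a generic scatter operator
#'
#' Fixed-point iteration
#' \deqn{P_L^{(k+1)} = r \cdot SC(E_L - P_L^{(k)}, E_M, E_U)}
#' starting from `P_L = 0`, where `SC` is any energy-window-based scatter
#' correction.  With the linear TEW operator the iteration converges
#' geometrically (ratio `alpha * r`) to the closed-form [tewdr()] result.
#'
#' @inheritParams tewdr
#' @param sc_operator Function of `(E_L, E_M, E_U)` returning a corrected
#'   main-window matrix.
#' @param k_max Maximum number of iterations.
#' @param tol Convergence tolerance on `max |P_L^(k+1) - P_L^(k)|`.
#' @return Corrected matrix `sc_operator(E_L - P_L, E_M, E_U)` at the
#'   converged spillover estimate, with attributes `iterations` and
#'   `converged`.
#' @export
iterative_sc <- function(E_L, E_M, E_U, r, sc_operator, k_max = 50,
                         tol = 1e-8) {
  stopifnot(is.function(sc_operator), k_max >= 1, r >= 0)
  check_same_shape(E_L, E_M, E_U)
  scale0 <- max(abs(E_L), abs(E_M), abs(E_U), 1)
  P <- array(0, dim = dim(as.array(E_L)))
  k <- 0L
  converged <- FALSE
  while (k < k_max) {
    Pn <- r * sc_operator(E_L - P, E_M, E_U)
    if (max(abs(Pn)) > 1e6 * scale0) {
      stop("iterative spillover correction diverged")
    }
    delta <- max(abs(Pn - P))
    P <- Pn
    k <- k + 1L
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- sc_operator(E_L - P, E_M, E_U)
  attr(out, "iterations") <- k
  attr(out, "converged") <- converged
  out
}
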