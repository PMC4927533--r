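# Shared fixtures, built in code.

default_ws <- make_default_windows()

tc_coeffs <- tew_coefficients(default_ws[["Tc-lower"]],
                              default_ws[["Tc-main"]],
                              default_ws[["intermediate"]])
i_coeffs <- tew_coefficients(default_ws[["intermediate"]],
                             default_ws[["I-main"]],
                             default_ws[["I-upper"]])

# A small five-window stack with smooth structure plus noise.
make_test_stack <- function(n = 16, seed = 1, base = c(100, 1000, 60, 800,
                                                       40)) {
  set.seed(seed)
  counts <- lapply(base, function(b) {
    matrix(stats::rpois(n * n, b), n, n)
  })
  names(counts) <- names(default_ws)
  window_stack(counts, pixel_mm = 2.8)
}

# Small planar acquisition used by simulator tests.
small_acq <- function(n_views = 1) {
  acquisition_spec(n_tan = 48, n_ax = 12, pixel_mm = 4, n_views = n_views)
}

# Detector response objects built once (responses are deterministic).
resp_tc_fixture <- isotope_response("Tc-99m", detector_params(),
                                    n_samples = 5e5, seed = 101)
resp_i_fixture <- isotope_response("I-123", detector_params(),
                                   n_samples = 5e5, seed = 102)
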