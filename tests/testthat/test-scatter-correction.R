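test_that("TEW reproduces the hand-evaluated example and is linear", {
  expect_equal(tew(100, 1000, 50, tc_coeffs), 820, tolerance = 1e-12)
  # zero sub-windows leave the main window unchanged
  m <- matrix(runif(12, 10, 50), 3, 4)
  z <- matrix(0, 3, 4)
  expect_equal(tew(z, m, z, tc_coeffs), m)
  # homogeneity and additivity
  set.seed(2)
  L <- matrix(rpois(12, 40), 3, 4); M <- matrix(rpois(12, 900), 3, 4)
  U <- matrix(rpois(12, 20), 3, 4)
  expect_equal(tew(3 * L, 3 * M, 3 * U, tc_coeffs),
               3 * tew(L, M, U, tc_coeffs), tolerance = 1e-12)
  expect_error(tew(matrix(0, 2, 2), matrix(0, 3, 3), matrix(0, 2, 2),
                   tc_coeffs), "shape")
})

test_that("TEWDR reduces to TEW at r = 0 and matches its worked example", {
  set.seed(3)
  L <- matrix(rpois(64, 100), 8, 8); M <- matrix(rpois(64, 1000), 8, 8)
  U <- matrix(rpois(64, 50), 8, 8)
  expect_identical(tewdr(L, M, U, tc_coeffs, 0), tew(L, M, U, tc_coeffs))
  expect_equal(tewdr(100, 1000, 50, tc_coeffs, 0.1),
               899.4814519345832, tolerance = 1e-10)
  expect_equal(tewdr(100, 1000, 50, tc_coeffs, 0.1),
               820 / (1 - tc_coeffs$alpha * 0.1), tolerance = 1e-12)
  # scatter-free primary input is a fixed point: E_L = r E_M, E_U = 0
  r <- 0.2
  expect_equal(tewdr(r * M, M, 0 * M, tc_coeffs, r), M, tolerance = 1e-10)
  expect_error(tewdr(L, M, U, tc_coeffs, 1 / tc_coeffs$alpha),
               "singular")
})

test_that("the two closed forms of TEWDR agree on randomized stacks", {
  # spillover-solved form vs TEW / (1 - alpha r), filter off
  set.seed(11)
  for (k in 1:200) {
    n <- sample(2:6, 1)
    L <- matrix(runif(n * n, 0, 500), n, n)
    M <- matrix(runif(n * n, 0, 5000), n, n)
    U <- matrix(runif(n * n, 0, 300), n, n)
    r <- runif(1, 0, 0.5)
    a <- tewdr(L, M, U, tc_coeffs, r)
    b <- tew(L, M, U, tc_coeffs) / (1 - tc_coeffs$alpha * r)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("Butterworth filter has the specified frequency response", {
  expect_equal(butterworth_gain(0), 1)
  expect_equal(butterworth_gain(0.056), 1 / sqrt(2), tolerance = 1e-12)
  expect_true(all(diff(butterworth_gain(seq(0, 0.5, by = 0.01))) < 0))
  # constant image is unchanged (DC gain 1), any padding
  for (pad in c("symmetric", "none")) {
    spec <- scatter_filter_spec(pad = pad)
    img <- matrix(3.7, 24, 24)
    expect_equal(butterworth_smooth(img, spec), img, tolerance = 1e-12)
  }
  # pure sinusoid at the cutoff frequency is attenuated by 1/sqrt(2)
  n <- 100
  cutoff <- 0.05  # 5 cycles over 100 samples: an exact DFT bin
  spec <- scatter_filter_spec(cutoff = cutoff, pad = "none")
  img <- outer(sin(2 * pi * cutoff * (0:(n - 1))), rep(1, 8))
  out <- butterworth_smooth(img, spec)
  expect_equal(max(abs(out)), max(abs(img)) / sqrt(2), tolerance = 1e-6)
  # white noise loses variance (gain <= 1 everywhere)
  set.seed(9)
  noise <- matrix(rnorm(64 * 64), 64, 64)
  sm <- butterworth_smooth(noise, scatter_filter_spec())
  expect_lt(var(as.vector(sm)), var(as.vector(noise)))
  # smoothing approximately preserves the mean with mirror padding
  expect_equal(mean(sm), mean(noise), tolerance = 0.05)
})

test_that("crosstalk estimate is the sensitivity-scaled I-main window", {
  resp <- resp_i_fixture
  E <- matrix(500, 4, 4)
  ct <- crosstalk(E, resp)
  for (w in names(ct$CI)) {
    expect_equal(ct$CI[[w]],
                 (resp$S[[w]] / resp$S[["I-main"]]) * E)
  }
  # zero I-main -> zero contamination
  ct0 <- crosstalk(matrix(0, 4, 4), resp)
  expect_true(all(vapply(ct0$CI, function(m) all(m == 0), logical(1))))
  # homogeneity
  ct2 <- crosstalk(2 * E, resp)
  expect_equal(ct2$CI[["Tc-main"]], 2 * ct$CI[["Tc-main"]])
  # synthetic response with a known ratio
  fake <- resp
  fake$S[] <- 0
  fake$S[c("Tc-main", "I-main")] <- c(0.1, 0.5)
  expect_equal(crosstalk(E, fake)$CI[["Tc-main"]], 0.2 * E)
})

test_that("FiveEW handles single-isotope stacks as expected", {
  # stack with zero I-related counts, r_Tc = 0, filter off: the Tc branch
  # is plain TEW and the I branch is identically zero
  st <- make_test_stack(base = c(100, 1000, 0, 0, 0))
  resp_tc0 <- resp_tc_fixture
  resp_tc0$r <- 0
  out <- five_ew(st, resp_tc0, resp_i_fixture, NULL, use_dr = TRUE)
  expect_equal(out$i_primary, st$counts[["I-main"]] * 0)
  expect_equal(out$tc_primary,
               tew(st$counts[["Tc-lower"]], st$counts[["Tc-main"]],
                   st$counts[["intermediate"]], tc_coeffs))
  expect_error(five_ew(window_stack(st$counts[1:4],
                                    validate_nonnegative = FALSE),
                       resp_tc_fixture, resp_i_fixture),
               "missing window")
})

test_that("FiveEW is homogeneous and its I branch ignores Tc windows", {
  st <- make_test_stack(seed = 8)
  filt <- scatter_filter_spec()
  out <- five_ew(st, resp_tc_fixture, resp_i_fixture, filt)
  # homogeneity of the whole chain
  st3 <- window_stack(lapply(st$counts, `*`, 3), pixel_mm = st$pixel_mm)
  out3 <- five_ew(st3, resp_tc_fixture, resp_i_fixture, filt)
  expect_equal(out3$tc_primary, 3 * out$tc_primary, tolerance = 1e-9)
  expect_equal(out3$i_primary, 3 * out$i_primary, tolerance = 1e-9)
  # adding counts to the Tc-related windows leaves i_primary bit-identical
  st2 <- st
  st2$counts[["Tc-lower"]] <- st2$counts[["Tc-lower"]] + 123
  st2$counts[["Tc-main"]] <- st2$counts[["Tc-main"]] * 5 + 7
  out2 <- five_ew(st2, resp_tc_fixture, resp_i_fixture, filt)
  expect_identical(out2$i_primary, out$i_primary)
})

test_that("detector-response correction only shrinks the scatter estimate", {
  # TEWDR >= TEW pointwise when 0 < alpha r < 1 and TEW >= 0
  set.seed(13)
  for (k in 1:50) {
    L <- matrix(runif(16, 0, 200), 4, 4)
    U <- matrix(runif(16, 0, 100), 4, 4)
    M <- matrix(runif(16, 0, 4000), 4, 4) +
      tc_coeffs$alpha * L + tc_coeffs$beta * U  # ensures TEW >= 0
    r <- runif(1, 0.01, 0.9 / tc_coeffs$alpha)
    expect_true(all(tewdr(L, M, U, tc_coeffs, r) >=
                      tew(L, M, U, tc_coeffs) - 1e-9))
  }
})

test_that("iterative spillover correction converges to the closed form", {
  set.seed(21)
  L <- matrix(rpois(36, 150), 6, 6); M <- matrix(rpois(36, 2000), 6, 6)
  U <- matrix(rpois(36, 60), 6, 6)
  sc_tew <- function(EL, EM, EU) tew(EL, EM, EU, tc_coeffs)
  r <- 0.25
  it <- iterative_sc(L, M, U, r, sc_tew, k_max = 200, tol = 1e-12)
  expect_true(attr(it, "converged"))
  expect_equal(as.vector(it), as.vector(tewdr(L, M, U, tc_coeffs, r)),
               tolerance = 1e-9)
  # r = 0 converges in one step to the bare operator
  it0 <- iterative_sc(L, M, U, 0, sc_tew)
  expect_equal(attr(it0, "iterations"), 1L)
  expect_equal(as.vector(it0), as.vector(sc_tew(L, M, U)))
  # geometric convergence with ratio alpha * r for the linear operator
  P <- 0
  deltas <- numeric(6)
  for (k in 1:6) {
    Pn <- r * sc_tew(L - P, M, U)
    deltas[k] <- max(abs(Pn - P))
    P <- Pn
  }
  ratios <- deltas[-1] / deltas[-6]
  expect_equal(ratios, rep(tc_coeffs$alpha * r, 5), tolerance = 1e-6)
})
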