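test_that("default window set matches the five-window acquisition scheme", {
  ws <- make_default_windows()
  expect_named(ws, c("Tc-lower", "Tc-main", "intermediate", "I-main",
                     "I-upper"))
  expect_equal(ws[["Tc-main"]]$lo, 130)
  expect_equal(ws[["Tc-main"]]$hi, 148)
  expect_equal(ws[["intermediate"]]$width, 5)
  expect_equal(ws[["Tc-lower"]]$center, 125)
  expect_equal(ws[["I-upper"]]$center, 175)
  # strictly increasing, non-overlapping (constructor validates; assert
  # the ordering is as expected)
  lo <- vapply(ws, `[[`, numeric(1), "lo")
  hi <- vapply(ws, `[[`, numeric(1), "hi")
  expect_true(all(diff(lo) > 0))
  expect_true(all(hi[-5] <= lo[-1]))
})

test_that("no energy belongs to two default windows (0.1-keV grid)", {
  ws <- make_default_windows()
  grid <- seq(100, 200, by = 0.1)
  hits <- sapply(ws, function(w) grid >= w$lo & grid < w$hi)
  expect_lte(max(rowSums(hits)), 1)
})

test_that("window constructors reject degenerate intervals", {
  expect_error(energy_window("bad", 148, 130), "strictly below")
  expect_error(energy_window_set(list(energy_window("a", 100, 130),
                                      energy_window("b", 120, 140))),
               "overlap")
  expect_error(energy_window_set(list(energy_window("a", 130, 140),
                                      energy_window("b", 100, 120))),
               "increasing")
})

test_that("TEW coefficients reproduce hand-evaluated values", {
  ws <- make_default_windows()
  co <- tew_coefficients(ws[["Tc-lower"]], ws[["Tc-main"]],
                         ws[["intermediate"]])
  expect_equal(co$alpha, 13.5 / 27.5 * 18 / 10, tolerance = 1e-12)
  expect_equal(co$beta, 14 / 27.5 * 18 / 5, tolerance = 1e-12)
  co_i <- tew_coefficients(ws[["intermediate"]], ws[["I-main"]],
                           ws[["I-upper"]])
  expect_equal(co_i$alpha, 5 / 3, tolerance = 1e-12)
  expect_equal(co_i$beta, 2 / 3, tolerance = 1e-12)
})

test_that("TEW coefficients: symmetry and scale invariance", {
  # symmetric equal-width windows, main centred midway
  L <- energy_window("L", 90, 110)
  M <- energy_window("M", 120, 150)
  U <- energy_window("U", 160, 180)
  co <- tew_coefficients(L, M, U)
  expect_equal(co$alpha, 0.5 * M$width / L$width)
  expect_equal(co$beta, 0.5 * M$width / U$width)
  # multiplying all energies by a constant leaves alpha, beta unchanged
  for (s in c(0.5, 2, 17.3)) {
    cos_ <- tew_coefficients(energy_window("L", 90 * s, 110 * s),
                             energy_window("M", 120 * s, 150 * s),
                             energy_window("U", 160 * s, 180 * s))
    expect_equal(cos_$alpha, co$alpha, tolerance = 1e-12)
    expect_equal(cos_$beta, co$beta, tolerance = 1e-12)
  }
  expect_error(tew_coefficients(U, M, L), "C_L < C_M < C_U")
})

test_that("bin_histogram routes counts to the right windows", {
  ws <- make_default_windows()
  edges <- default_energy_edges()
  nb <- length(edges) - 1L
  # all counts at 141 keV -> everything in Tc-main
  h <- array(0, dim = c(nb, 2, 2))
  h[which(edges == 141), , ] <- 7
  st <- bin_histogram(energy_histogram(h, edges), ws)
  expect_equal(sum(st$counts[["Tc-main"]]), 7 * 4)
  others <- setdiff(names(ws), "Tc-main")
  expect_true(all(vapply(st$counts[others], sum, numeric(1)) == 0))
  # counts at 149 keV fall in the 148-150 gap: no window
  h2 <- array(0, dim = c(nb, 1, 1))
  h2[which(edges == 149), , ] <- 5
  st2 <- bin_histogram(energy_histogram(h2, edges), ws)
  expect_true(all(vapply(st2$counts, sum, numeric(1)) == 0))
  # uniform unit density 120-180 -> counts proportional to widths
  h3 <- array(0, dim = c(nb, 1, 1))
  h3[edges[-length(edges)] >= 120 & edges[-1] <= 180, 1, 1] <- 1
  st3 <- bin_histogram(energy_histogram(h3, edges), ws)
  expect_equal(unname(vapply(st3$counts, sum, numeric(1))),
               c(10, 18, 5, 15, 10))
})

test_that("bin_histogram is additive and rejects misaligned edges", {
  ws <- make_default_windows()
  edges <- default_energy_edges()
  nb <- length(edges) - 1L
  set.seed(4)
  h1 <- array(rpois(nb * 4, 3), dim = c(nb, 2, 2))
  h2 <- array(rpois(nb * 4, 5), dim = c(nb, 2, 2))
  s1 <- bin_histogram(energy_histogram(h1, edges), ws)
  s2 <- bin_histogram(energy_histogram(h2, edges), ws)
  s12 <- bin_histogram(energy_histogram(h1 + h2, edges), ws)
  for (w in names(ws)) {
    expect_equal(s12$counts[[w]], s1$counts[[w]] + s2$counts[[w]])
  }
  # binned total never exceeds the histogram total (gap energies dropped)
  expect_lte(sum(vapply(s12$counts, sum, numeric(1))), sum(h1 + h2))
  # half-keV-shifted edges do not align with the window bounds
  bad_edges <- edges + 0.5
  expect_error(bin_histogram(energy_histogram(h1, bad_edges), ws),
               "align")
})

test_that("window sets round-trip through JSON", {
  ws <- make_default_windows()
  txt <- windows_to_json(ws)
  ws2 <- windows_from_json(txt)
  expect_equal(ws2, ws)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  windows_to_json(ws, path)
  expect_equal(windows_from_json(path), ws)
})
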