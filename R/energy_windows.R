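# Canonical ordering of the five acquisition windows.  The intermediate
# window is shared: it acts as the upper sub-window for Tc-99m and the lower
# sub-window for I-123.
FIVEEW_WINDOW_NAMES <- c("Tc-lower", "Tc-main", "intermediate",
                         "I-main", "I-upper")

#' Define an energy window
#'
#' An energy window is a half-open interval `[lo, hi)` in keV.  Half-open
#' intervals are used throughout so that adjacent windows sharing a bound
#' (e.g. 130 keV between Tc-lower and Tc-main) never double-count an event.
#'
#' @param name Window label.
#' @param lo Lower bound in keV (inclusive).
#' @param hi Upper bound in keV (exclusive).
#' @return An `energy_window` object with derived fields `center`
#'   (arithmetic midpoint, keV) and `width` (keV).
#' @examples
#' energy_window("Tc-main", 130, 148)
#' @export
energy_window <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lo), length(lo) == 1L, is.finite(lo),
            is.numeric(hi), length(hi) == 1L, is.finite(hi))
  if (!(lo < hi)) {
    stop("invalid energy window '", name, "': lo (", lo,
         ") must be strictly below hi (", hi, ")")
  }
  w <- list(name = name, lo = lo, hi = hi,
            center = (lo + hi) / 2, width = hi - lo)
  class(w) <- "energy_window"
  w
}

#' @export
print.energy_window <- function(x, ...) {
  cat(sprintf("<energy_window> %s: [%g, %g) keV  centre %g  width %g\n",
              x$name, x$lo, x$hi, x$center, x$width))
  invisible(x)
}

#' Build an ordered, non-overlapping energy window set
#'
#' @param windows List of [energy_window()] objects, in increasing energy
#'   order.
#' @return An `energy_window_set` (named list of windows).
#' @export
energy_window_set <- function(windows) {
  stopifnot(is.list(windows), length(windows) >= 1L)
  ok <- vapply(windows, inherits, logical(1), "energy_window")
  if (!all(ok)) stop("all elements must be energy_window objects")
  nm <- vapply(windows, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("window names must be unique")
  lo <- vapply(windows, `[[`, numeric(1), "lo")
  hi <- vapply(windows, `[[`, numeric(1), "hi")
  if (is.unsorted(lo, strictly = TRUE)) {
    stop("windows must be supplied in increasing energy order")
  }
  if (any(hi[-length(hi)] > lo[-1] + 1e-12)) {
    stop("windows overlap: ", paste(nm, collapse = ", "))
  }
  names(windows) <- nm
  class(windows) <- "energy_window_set"
  windows
}

#' @export
print.energy_window_set <- function(x, ...) {
  cat("<energy_window_set> with", length(x), "windows\n")
  for (w in x) {
    cat(sprintf("  %-13s [%g, %g) keV\n", w$name, w$lo, w$hi))
  }
  invisible(x)
}

#' The default five-window scheme for simultaneous Tc-99m / I-123 imaging
#'
#' Returns the five acquisition windows used by the FiveEW correction:
#' Tc-lower 120--130, Tc-main 130--148, intermediate (shared Tc-upper /
#' I-lower) 150--155, I-main 155--170 and I-upper 170--180 keV.  The
#' 148--150 keV gap and energies above 180 keV belong to no window and are
#' discarded at binning time.
#'
#' @return An [energy_window_set()] of the five windows.
#' @examples
#' ws <- make_default_windows()
#' ws[["Tc-main"]]$width  # 18 keV
#' @export
make_default_windows <- function() {
  energy_window_set(list(
    energy_window("Tc-lower",     120, 130),
    energy_window("Tc-main",      130, 148),
    energy_window("intermediate", 150, 155),
    energy_window("I-main",       155, 170),
    energy_window("I-upper",      170, 180)
  ))
}

#' Triple-energy-window coefficients
#'
#' Computes the sub-window weights of the TEW scatter estimate for a
#' (lower, main, upper) window triple:
#' \deqn{\alpha = \frac{C_U - C_M}{C_U - C_L} \cdot \frac{W_M}{W_L}, \qquad
#'       \beta  = \frac{C_M - C_L}{C_U - C_L} \cdot \frac{W_M}{W_U}}
#' where `C` are window centres and `W` window widths.  The coefficients are
#' invariant under a common rescaling of all energies.
#'
#' @param L,M,U Lower, main and upper [energy_window()] objects with
#'   strictly increasing centres.
#' @return A `tew_coefficients` object (fields `alpha`, `beta`).
#' @examples
#' ws <- make_default_windows()
#' tew_coefficients(ws[["Tc-lower"]], ws[["Tc-main"]], ws[["intermediate"]])
#' @export
tew_coefficients <- function(L, M, U) {
  stopifnot(inherits(L, "energy_window"), inherits(M, "energy_window"),
            inherits(U, "energy_window"))
  if (!(L$center < M$center && M$center < U$center)) {
    stop("invalid window triple: centres must satisfy C_L < C_M < C_U ",
         sprintf("(got %g, %g, %g)", L$center, M$center, U$center))
  }
  alpha <- (U$center - M$center) / (U$center - L$center) * M$width / L$width
  beta  <- (M$center - L$center) / (U$center - L$center) * M$width / U$width
  out <- list(alpha = alpha, beta = beta,
              windows = c(L = L$name, M = M$name, U = U$name))
  class(out) <- "tew_coefficients"
  out
}

#' @export
print.tew_coefficients <- function(x, ...) {
  cat(sprintf("<tew_coefficients> (%s, %s, %s): alpha = %.6f, beta = %.6f\n",
              x$windows["L"], x$windows["M"], x$windows["U"],
              x$alpha, x$beta))
  invisible(x)
}

#' Per-pixel energy histograms
#'
#' Container for per-pixel deposited-energy histograms.  `counts` is an
#' array whose first dimension indexes energy bins; remaining dimensions
#' are detector pixels (tangential x axial).  Bin edges default to 1-keV
#' bins from 20 to 550 keV, so every default window bound falls exactly on
#' a bin edge and binning requires no interpolation.
#'
#' @param counts Array with energy bins along the first dimension.
#' @param edges Numeric vector of bin edges (length `dim(counts)[1] + 1`).
#' @param pixel_mm Detector pixel pitch in mm.
#' @return An `energy_histogram` object.
#' @export
energy_histogram <- function(counts, edges = default_energy_edges(),
                             pixel_mm = 1.4) {
  counts <- as.array(counts)
  if (length(edges) != dim(counts)[1] + 1L) {
    stop("edges must have length dim(counts)[1] + 1")
  }
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  structure(list(counts = counts, edges = as.numeric(edges),
                 pixel_mm = pixel_mm),
            class = "energy_histogram")
}

#' Default energy-bin edges (1-keV bins, 20--550 keV)
#' @return Numeric vector of bin edges in keV.
#' @export
default_energy_edges <- function() seq(20, 550, by = 1)

#' Stack of per-window count matrices
#'
#' A `window_stack` holds one count matrix per energy window, co-registered
#' on the detector grid.  Matrices are 2-D (tangential x axial) for a single
#' projection view, or 3-D (tangential x axial x view) for a full rotation.
#'
#' @param counts Named list of count arrays, one per window, all of one
#'   shape.
#' @param pixel_mm Pixel pitch in mm.
#' @param view_angles Optional numeric vector of view angles in degrees.
#' @param isotope Optional isotope tag.
#' @param validate_nonnegative If `TRUE` (the default for raw acquisition
#'   data) negative counts are rejected; corrected stacks may carry
#'   negatives and should pass `FALSE`.
#' @return A `window_stack` object.
#' @export
window_stack <- function(counts, pixel_mm = 1.4, view_angles = NULL,
                         isotope = NULL, validate_nonnegative = TRUE) {
  stopifnot(is.list(counts), length(counts) >= 1L, !is.null(names(counts)))
  counts <- lapply(counts, as.array)
  dims <- lapply(counts, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all window matrices must share one shape")
  }
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (!all(is.finite(x))) stop("non-finite counts in window '", nm, "'")
    if (validate_nonnegative && any(x < 0)) {
      stop("negative counts in raw window '", nm, "'")
    }
  }
  structure(list(counts = counts, pixel_mm = pixel_mm,
                 view_angles = view_angles, isotope = isotope),
            class = "window_stack")
}

#' @export
print.window_stack <- function(x, ...) {
  d <- dim(x$counts[[1]])
  cat("<window_stack>", paste(d, collapse = " x "), "pixels;",
      length(x$counts), "windows:", paste(names(x$counts), collapse = ", "),
      "\n")
  tot <- vapply(x$counts, sum, numeric(1))
  cat("  totals:", paste(sprintf("%s=%.4g", names(tot), tot),
                         collapse = ", "), "\n")
  invisible(x)
}

# Map each histogram bin (by its centre) to a window index, 0 = unassigned.
window_bin_index <- function(edges, ws) {
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- integer(length(centers))
  for (i in seq_along(ws)) {
    w <- ws[[i]]
    idx[centers >= w$lo & centers < w$hi] <- i
  }
  idx
}

# Check that every window bound coincides with a histogram bin edge.
check_edge_alignment <- function(edges, ws, tol = 1e-9) {
  bounds <- unlist(lapply(ws, function(w) c(w$lo, w$hi)))
  for (b in bounds) {
    if (min(abs(edges - b)) > tol) {
      stop("window bound ", b, " keV does not align with a histogram bin ",
           "edge; re-bin the histogram (no silent interpolation is done)")
    }
  }
  if (min(bounds) < min(edges) - tol || max(bounds) > max(edges) + tol) {
    stop("histogram energy range does not cover all window bounds")
  }
  invisible(TRUE)
}

#' Bin per-pixel energy histograms into window count matrices
#'
#' Sums the histogram bins whose centres fall inside each window of `ws`.
#' Bin edges must align exactly with the window bounds; energies in the
#' inter-window gaps (148--150 keV and above 180 keV for the default set)
#' are discarded.
#'
#' @param hist An [energy_histogram()] (or a plain array plus `edges`).
#' @param ws An [energy_window_set()].
#' @param edges Bin edges, only used when `hist` is a plain array.
#' @param ... Passed to [window_stack()].
#' @return A [window_stack()] with one matrix per window.
#' @export
bin_histogram <- function(hist, ws = make_default_windows(), edges = NULL,
                          ...) {
  if (inherits(hist, "energy_histogram")) {
    counts <- hist$counts
    edges <- hist$edges
    pixel_mm <- hist$pixel_mm
  } else {
    counts <- as.array(hist)
    if (is.null(edges)) stop("edges required for a plain array histogram")
    pixel_mm <- 1.4
  }
  check_edge_alignment(edges, ws)
  idx <- window_bin_index(edges, ws)
  d <- dim(counts)
  npix <- prod(d[-1])
  flat <- matrix(counts, nrow = d[1], ncol = npix)
  out <- vector("list", length(ws))
  names(out) <- names(ws)
  pixdim <- if (length(d) > 1L) d[-1] else 1L
  for (i in seq_along(ws)) {
    rows <- which(idx == i)
    s <- if (length(rows) == 1L) flat[rows, ] else colSums(flat[rows, ,
                                                                drop = FALSE])
    out[[i]] <- array(s, dim = pixdim)
  }
  window_stack(out, pixel_mm = pixel_mm, validate_nonnegative = FALSE, ...)
}

#' Serialize / restore an energy window set as JSON
#'
#' @param ws An [energy_window_set()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `windows_to_json` returns the path (invisibly) or a JSON string;
#'   `windows_from_json` returns an [energy_window_set()].
#' @export
windows_to_json <- function(ws, path = NULL) {
  df <- data.frame(name = vapply(ws, `[[`, character(1), "name"),
                   lo = vapply(ws, `[[`, numeric(1), "lo"),
                   hi = vapply(ws, `[[`, numeric(1), "hi"))
  txt <- jsonlite::toJSON(df, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname windows_to_json
#' @param json JSON string or file path produced by [windows_to_json()].
#' @export
windows_from_json <- function(json) {
  df <- jsonlite::fromJSON(json)
  energy_window_set(lapply(seq_len(nrow(df)), function(i) {
    energy_window(df$name[i], df$lo[i], df$hi[i])
  }))
}
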