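# Readers and writers for the pipeline artifacts: projection stacks
# (single-file RDS container with a version field), detector-response
# spectra (two-column text + JSON sidecar), volumes (NIfTI) and reports
# (CSV).

STACK_FORMAT <- "fiveew-stack"
STACK_VERSION <- 1L

#' Write / read a projection-stack container
#'
#' Stacks are stored as a single-file container holding one dataset per
#' energy window, optional ground-truth primary stacks, and a metadata
#' block (pixel pitch, view angles, seed).  Reading verifies the format
#' tag and version and reproduces counts bit-exactly.
#'
#' @param stack A [window_stack()].
#' @param path Output file path.
#' @param truth Optional named list of ground-truth [window_stack()]s.
#' @param meta Optional metadata list (stored verbatim).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   list with `stack`, `truth`, `meta`.
#' @export
write_stack <- function(stack, path, truth = NULL, meta = list()) {
  stopifnot(inherits(stack, "window_stack"))
  obj <- list(format = STACK_FORMAT, version = STACK_VERSION,
              stack = stack, truth = truth, meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read '", path, "' as a projection-stack container: ",
         conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, STACK_FORMAT)) {
    stop("'", path, "' is not a ", STACK_FORMAT, " container ",
         "(missing format tag)")
  }
  if (!identical(obj$version, STACK_VERSION)) {
    stop("unsupported ", STACK_FORMAT, " version: ", obj$version)
  }
  obj[c("stack", "truth", "meta")]
}

#' Write / read a reconstructed volume as NIfTI
#'
#' Voxel size metadata is preserved through the NIfTI header.
#'
#' @param vol A [spect_volume()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `write_volume` returns the path invisibly; `read_volume` a
#'   [spect_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "spect_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- rep(vol$voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spect_volume(array(as.numeric(img), dim = dim(img)),
               voxel_mm = RNifti::pixdim(img)[1])
}

#' Write / read a detector response
#'
#' The spectrum goes to `<path>.tsv` (keV, normalized counts); the window
#' sensitivities, spillover ratio, detector parameters and seed go to a
#' JSON sidecar `<path>.json`.
#'
#' @param resp A `detector_response`.
#' @param path Base path (without extension).
#' @return `write_response` returns the base path invisibly;
#'   `read_response` a `detector_response`.
#' @export
write_response <- function(resp, path) {
  stopifnot(inherits(resp, "detector_response"))
  df <- data.frame(energy_kev = resp$energies, density = resp$spectrum)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- list(isotope = resp$isotope, S = as.list(resp$S), r = resp$r,
               params = unclass(resp$params), seed = resp$seed,
               edges = resp$edges)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_response
#' @export
read_response <- function(path) {
  df <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  params <- if (!is.null(side$params)) do.call(detector_params,
                                               as.list(side$params))
  resp <- response_from_spectrum(df$density, side$edges,
                                 isotope = side$isotope,
                                 params = params, seed = side$seed)
  resp
}

#' Write / read an analysis report as CSV
#'
#' @param report A data frame.
#' @param path CSV path.
#' @return `write_report` returns `path` invisibly; `read_report` a data
#'   frame.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) utils::read.csv(path)
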