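# End-to-end pipeline: simulate -> correct -> reconstruct -> analyze,
# driven by a validated JSON-style configuration.

#' Default run configuration
#'
#' A complete configuration for a scaled-down rotating acquisition of the
#' uniform cylinder phantom with both isotopes, FiveEW correction and OSEM
#' reconstruction.  All fields can be overridden; [validate_config()]
#' documents the schema.
#'
#' @return A nested configuration list.
#' @export
default_run_config <- function() {
  list(
    phantom = list(type = "cylinder", inner_diameter = 200, length = 200,
                   activity_tc = 30, activity_i = 20, voxel_mm = 4),
    acquisition = list(n_tan = 64, n_ax = 16, pixel_mm = 4,
                       rotation_radius = 130, n_views = 60, arc = 360,
                       hole_mm = 2.4, hole_pitch_mm = 2.8,
                       collimator_mm = 26, duration_s = 180),
    detector = list(),  # overrides for detector_params()
    simulate = list(mode = "spect", n_photons = 2e6,
                    n_photons_per_view = 5e4, include_scatter = TRUE,
                    response_samples = 5e5),
    correction = list(method = "fiveew",
                      filter = list(order = 8, cutoff = 0.056,
                                    enabled = TRUE)),
    osem = list(n_subsets = 30, n_iterations = 8, psf = FALSE,
                postfilter_fwhm = 14, mu_tc = 0.015, mu_i = 0.0146),
    seed = 1
  )
}

#' Validate a run configuration
#'
#' Checks the configuration against the published schema
#' (`inst/schema/run-config.json`): required blocks, field types and value
#' ranges.  Errors name the offending stage and field.
#'
#' @param cfg Configuration list (e.g. from [read_config()]).
#' @return The validated configuration, with defaults filled in,
#'   invisibly.
#' @export
validate_config <- function(cfg) {
  base <- default_run_config()
  need <- function(block) {
    if (!is.null(cfg[[block]]) && !is.list(cfg[[block]])) {
      stop("config: '", block, "' must be a block (object)")
    }
    utils::modifyList(base[[block]], as.list(cfg[[block]]))
  }
  out <- list(phantom = need("phantom"), acquisition = need("acquisition"),
              detector = as.list(cfg$detector),
              simulate = need("simulate"), correction = need("correction"),
              osem = need("osem"),
              seed = if (is.null(cfg$seed)) base$seed else cfg$seed)
  if (!out$phantom$type %in% c("cylinder", "six-compartment", "line")) {
    stop("config phantom: unknown type '", out$phantom$type, "'")
  }
  if (!out$simulate$mode %in% c("planar", "spect")) {
    stop("config simulate: mode must be 'planar' or 'spect'")
  }
  if (!out$correction$method %in% c("none", "tew", "fiveew",
                                    "fiveew-wodr")) {
    stop("config correction: unknown method '", out$correction$method, "'")
  }
  with(out$osem, {
    if (n_subsets < 1 || n_iterations < 1) {
      stop("config osem: subsets and iterations must be >= 1")
    }
  })
  if (out$simulate$mode == "spect" &&
      out$acquisition$n_views %% out$osem$n_subsets != 0) {
    stop("config osem: n_subsets must divide acquisition n_views")
  }
  if (!is.numeric(out$seed) || length(out$seed) != 1) {
    stop("config: seed must be a single integer")
  }
  invisible(out)
}

#' Read a JSON run configuration
#'
#' @param path JSON file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

build_phantom <- function(pc) {
  switch(pc$type,
    "cylinder" = make_cylinder_phantom(
      inner_diameter = pc$inner_diameter, length = pc$length,
      activity_tc = pc$activity_tc, activity_i = pc$activity_i,
      voxel_mm = pc$voxel_mm),
    "line" = make_line_phantom(
      length = pc$length, activity_tc = pc$activity_tc,
      activity_i = pc$activity_i, voxel_mm = pc$voxel_mm),
    "six-compartment" = make_six_compartment_phantom(voxel_mm =
                                                       pc$voxel_mm)
  )
}

build_acquisition <- function(ac, seed) {
  do.call(acquisition_spec, c(ac, list(seed = seed)))
}

#' Run the configured pipeline
#'
#' Executes simulate -> correct -> reconstruct -> analyze and writes every
#' artifact, the resolved configuration and a run manifest (config hash,
#' seed, package version) to `out_dir`.  Identical configuration and seed
#' give byte-identical stacks and reports.
#'
#' @param cfg Configuration (validated with [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @param verbose Print per-stage progress and count totals.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir,
                         verbose = TRUE) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]

  ## resolved config + manifest -----------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), cfg_path)
  paths$config <- cfg_path

  ## simulate ------------------------------------------------------------
  phantom <- build_phantom(cfg$phantom)
  acq <- build_acquisition(cfg$acquisition, cfg$seed)
  det <- do.call(detector_params, cfg$detector)
  ws <- make_default_windows()
  say("[simulate] %s, mode=%s, seed=%d", cfg$phantom$type,
      cfg$simulate$mode, as.integer(cfg$seed))
  if (cfg$simulate$mode == "planar") {
    lh <- simulate_planar(phantom, acq, det,
                          n_photons = cfg$simulate$n_photons,
                          seed = cfg$seed,
                          include_scatter = cfg$simulate$include_scatter)
    stack <- histograms_to_stack(lh, ws)
    truth <- lapply(stats::setNames(nm = names(lh$histograms)),
                    function(iso) histograms_to_stack(lh, ws, "primary",
                                                      iso))
    angles <- 0
  } else {
    sim <- simulate_spect(phantom, acq, det,
                          n_photons_per_view =
                            cfg$simulate$n_photons_per_view,
                          seed = cfg$seed,
                          include_scatter = cfg$simulate$include_scatter)
    stack <- sim$stack
    truth <- sim$truth
    angles <- view_angles(acq)
  }
  say("[simulate] total counts: %s",
      paste(sprintf("%s=%.4g", names(stack$counts),
                    vapply(stack$counts, sum, numeric(1))),
            collapse = ", "))
  paths$stack <- file.path(out_dir, "stack.rds")
  write_stack(stack, paths$stack, truth = truth,
              meta = list(seed = cfg$seed, phantom = cfg$phantom$type))

  ## correct -------------------------------------------------------------
  method <- cfg$correction$method
  say("[correct] method=%s", method)
  fs <- cfg$correction$filter
  filt <- scatter_filter_spec(order = fs$order, cutoff = fs$cutoff,
                              enabled = isTRUE(fs$enabled))
  resp_tc <- isotope_response("Tc-99m", det,
                              n_samples = cfg$simulate$response_samples,
                              seed = derive_seed(cfg$seed, 901L))
  resp_i <- isotope_response("I-123", det,
                             n_samples = cfg$simulate$response_samples,
                             seed = derive_seed(cfg$seed, 902L))
  paths$response_tc <- file.path(out_dir, "response_tc")
  paths$response_i <- file.path(out_dir, "response_i")
  write_response(resp_tc, paths$response_tc)
  write_response(resp_i, paths$response_i)
  corrected <- correct_stack(stack, method, resp_tc, resp_i, filt, ws)
  paths$corrected <- file.path(out_dir, "corrected.rds")
  write_stack(window_stack(corrected, pixel_mm = stack$pixel_mm,
                           view_angles = stack$view_angles,
                           validate_nonnegative = FALSE),
              paths$corrected, meta = list(method = method))

  ## reconstruct ---------------------------------------------------------
  vols <- list()
  if (cfg$simulate$mode == "spect") {
    for (iso in c("Tc-99m", "I-123")) {
      p <- corrected[[iso]]
      if (sum(pmax(p, 0)) <= 0) next
      mu_v <- if (iso == "Tc-99m") cfg$osem$mu_tc else cfg$osem$mu_i
      say("[reconstruct] %s OSEM %dx%d", iso, cfg$osem$n_subsets,
          cfg$osem$n_iterations)
      att <- trace_attenuation_map(stack, mu_value = mu_v, acq = acq)
      ocfg <- osem_config(cfg$osem$n_subsets, cfg$osem$n_iterations,
                          cfg$osem$psf, cfg$osem$postfilter_fwhm)
      vols[[iso]] <- osem(p, att, acq, ocfg)
      paths[[paste0("volume_", iso)]] <-
        file.path(out_dir, sprintf("volume_%s.nii.gz",
                                   gsub("[^A-Za-z0-9]", "", iso)))
      write_volume(vols[[iso]], paths[[paste0("volume_", iso)]])
    }
  }

  ## analyze -------------------------------------------------------------
  report <- NULL
  if (length(vols)) {
    dim_vol <- dim(vols[[1]]$values)
    voxel_mm <- vols[[1]]$voxel_mm
    rois <- if (cfg$phantom$type == "six-compartment") {
      six_compartment_rois(dim_vol, voxel_mm, phantom = phantom)
    } else {
      ax_len <- min(100, dim_vol[3] * voxel_mm * 0.6)
      uniform_phantom_rois(dim_vol, voxel_mm, roi_length_mm = ax_len)
    }
    for (iso in names(vols)) {
      st <- roi_stats(vols[[iso]], rois)
      st$isotope <- iso
      st$method <- method
      report <- rbind(report, st)
    }
    paths$report <- file.path(out_dir, "report.csv")
    write_report(report, paths$report)
    say("[analyze] %d ROI rows -> %s", nrow(report), paths$report)
  }

  ## manifest ------------------------------------------------------------
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("fiveew")),
    elapsed_s = round(proc.time()[3] - t0, 2),
    artifacts = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths$manifest)
  invisible(paths)
}

#' Apply a correction method to a five-window stack
#'
#' Dispatch helper used by the pipeline and the CLI: returns per-isotope
#' corrected (or uncorrected) main-window projections.
#'
#' @param stack A [window_stack()] with the five windows.
#' @param method `"none"`, `"tew"`, `"fiveew"` or `"fiveew-wodr"`.
#' @param resp_tc,resp_i Detector responses (ignored for `"none"`/`"tew"`).
#' @param filt A [scatter_filter_spec()] or `NULL`.
#' @param ws Window set.
#' @return Named list with elements `"Tc-99m"` and `"I-123"`.
#' @export
correct_stack <- function(stack, method, resp_tc = NULL, resp_i = NULL,
                          filt = NULL, ws = make_default_windows()) {
  E <- stack$counts
  switch(method,
    "none" = list("Tc-99m" = E[["Tc-main"]], "I-123" = E[["I-main"]]),
    "tew" = {
      co_tc <- tew_coefficients(ws[["Tc-lower"]], ws[["Tc-main"]],
                                ws[["intermediate"]])
      co_i <- tew_coefficients(ws[["intermediate"]], ws[["I-main"]],
                               ws[["I-upper"]])
      list("Tc-99m" = tewdr(E[["Tc-lower"]], E[["Tc-main"]],
                            E[["intermediate"]], co_tc, 0, filt),
           "I-123" = tewdr(E[["intermediate"]], E[["I-main"]],
                           E[["I-upper"]], co_i, 0, filt))
    },
    "fiveew" = ,
    "fiveew-wodr" = {
      res <- five_ew(stack, resp_tc, resp_i, filt,
                     use_dr = method == "fiveew", ws = ws)
      list("Tc-99m" = res$tc_primary, "I-123" = res$i_primary)
    },
    stop("unknown correction method '", method, "'")
  )
}
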