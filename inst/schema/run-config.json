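{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "fiveew run configuration",
  "type": "object",
  "properties": {
    "phantom": {
      "type": "object",
      "properties": {
        "type": {"enum": ["cylinder", "six-compartment", "line"]},
        "inner_diameter": {"type": "number", "exclusiveMinimum": 0},
        "length": {"type": "number", "exclusiveMinimum": 0},
        "activity_tc": {"type": "number", "minimum": 0},
        "activity_i": {"type": "number", "minimum": 0},
        "voxel_mm": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "acquisition": {
      "type": "object",
      "properties": {
        "n_tan": {"type": "integer", "minimum": 1},
        "n_ax": {"type": "integer", "minimum": 1},
        "pixel_mm": {"type": "number", "exclusiveMinimum": 0},
        "rotation_radius": {"type": "number", "exclusiveMinimum": 0},
        "n_views": {"type": "integer", "minimum": 1},
        "arc": {"type": "number", "exclusiveMinimum": 0},
        "hole_mm": {"type": "number", "exclusiveMinimum": 0},
        "hole_pitch_mm": {"type": "number", "exclusiveMinimum": 0},
        "collimator_mm": {"type": "number", "exclusiveMinimum": 0},
        "duration_s": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "detector": {
      "type": "object",
      "description": "overrides for detector_params(); see its manual page"
    },
    "simulate": {
      "type": "object",
      "properties": {
        "mode": {"enum": ["planar", "spect"]},
        "n_photons": {"type": "number", "minimum": 1},
        "n_photons_per_view": {"type": "number", "minimum": 1},
        "include_scatter": {"type": "boolean"},
        "response_samples": {"type": "number", "minimum": 1}
      }
    },
    "correction": {
      "type": "object",
      "properties": {
        "method": {"enum": ["none", "tew", "fiveew", "fiveew-wodr"]},
        "filter": {
          "type": "object",
          "properties": {
            "order": {"type": "number", "minimum": 1},
            "cutoff": {"type": "number", "exclusiveMinimum": 0,
                       "exclusiveMaximum": 0.5},
            "enabled": {"type": "boolean"}
          }
        }
      }
    },
    "osem": {
      "type": "object",
      "properties": {
        "n_subsets": {"type": "integer", "minimum": 1},
        "n_iterations": {"type": "integer", "minimum": 1},
        "psf": {"type": "boolean"},
        "postfilter_fwhm": {"type": "number", "minimum": 0},
        "mu_tc": {"type": "number", "minimum": 0},
        "mu_i": {"type": "number", "minimum": 0}
      }
    },
    "seed": {"type": "integer"}
  }
}
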