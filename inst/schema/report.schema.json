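{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "wagglemap pipeline report",
  "type": "object",
  "required": ["n_phases", "n_dances", "dance_rate_per_min", "calibration",
               "diagnostics", "sector_width_deg", "search_area"],
  "properties": {
    "n_phases": {"type": "integer", "minimum": 0},
    "n_dances": {"type": "integer", "minimum": 0},
    "dance_rate_per_min": {"type": "number", "minimum": 0},
    "dance_rate_rounded": {"type": "integer", "minimum": 0},
    "calibration": {
      "type": "object",
      "required": ["v"],
      "properties": {
        "v": {"type": "number", "exclusiveMinimum": 0},
        "v_rounded": {"type": "number"},
        "estimator": {"type": "string"},
        "n": {"type": ["integer", "null"]}
      }
    },
    "diagnostics": {
      "type": "object",
      "required": ["ring_spacing_m", "waggle_accuracy_m", "nyquist_margin",
                   "sampling_sufficient"],
      "properties": {
        "ring_spacing_m": {"type": "number", "exclusiveMinimum": 0},
        "ring_spacing_m_rounded": {"type": "integer"},
        "waggle_accuracy_m": {"type": "number", "exclusiveMinimum": 0},
        "waggle_accuracy_m_rounded": {"type": "integer"},
        "nyquist_margin": {"type": "number", "exclusiveMinimum": 0},
        "nyquist_adequate": {"type": "boolean"},
        "sampling_sufficient": {"type": "boolean"}
      }
    },
    "sector_width_deg": {"type": "number", "minimum": 0, "maximum": 360},
    "coverage_fraction": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
    "search_area": {
      "type": "object",
      "required": ["peak_lat_deg", "peak_lon_deg", "diameter_m"],
      "properties": {
        "peak_lat_deg": {"type": "number", "minimum": -90, "maximum": 90},
        "peak_lon_deg": {"type": "number", "minimum": -180, "maximum": 180},
        "center_lat_deg": {"type": "number"},
        "center_lon_deg": {"type": "number"},
        "diameter_m": {"type": "number", "minimum": 0},
        "n_endpoints": {"type": "integer", "minimum": 0}
      }
    }
  }
}
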