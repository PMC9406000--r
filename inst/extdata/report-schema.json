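{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "shiftbind pipeline report",
  "type": "object",
  "required": ["report", "metadata"],
  "properties": {
    "report": {
      "type": "object",
      "required": ["schema_version", "csp", "significance", "fits", "occupancy"],
      "properties": {
        "schema_version": {"const": "1.0"},
        "csp": {
          "type": "object",
          "required": ["n_points", "ligand_conc_mm", "n_residues",
                       "n_tracked_observations", "scale_n"],
          "properties": {
            "ligand_conc_mm": {"type": "array", "items": {"type": "number"},
                               "description": "mM"},
            "scale_n": {"type": "number", "exclusiveMinimum": 0}
          }
        },
        "significance": {
          "type": "object",
          "required": ["point_index", "ligand_conc_mm", "mean_ppm",
                       "sd_ppm", "threshold_ppm", "flagged"]
        },
        "fits": {
          "type": "object",
          "additionalProperties": {
            "type": "object",
            "required": ["site_id", "residues", "kd_mm", "r_squared",
                         "p_value", "n_obs", "converged"],
            "properties": {
              "kd_mm": {"type": "number", "exclusiveMinimum": 0},
              "r_squared": {"type": "number", "minimum": 0, "maximum": 1},
              "p_value": {"type": "number", "exclusiveMinimum": 0,
                          "maximum": 1}
            }
          }
        },
        "occupancy": {
          "type": "object",
          "additionalProperties": {
            "type": "object",
            "required": ["site_id", "ligand_conc", "kd", "fraction_bound",
                         "percent"],
            "properties": {
              "fraction_bound": {"type": "number", "minimum": 0,
                                 "maximum": 1}
            }
          }
        },
        "kd_ratios": {"type": "object"},
        "contacts": {
          "type": ["object", "null"],
          "description": "distances in Angstrom, fractions exact frame ratios"
        }
      }
    },
    "metadata": {
      "type": "object",
      "description": "run metadata (timestamps live here, never in report)"
    }
  }
}
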