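{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "egressr analysis report",
  "description": "Machine-readable report written by egressr::write_report(); schema_version 1.0",
  "type": "object",
  "required": ["per_width", "groups", "group_summary", "provenance"],
  "properties": {
    "per_width": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["width_cm", "n_intervals", "mean_interval_s", "Q",
                     "alpha", "beta", "epsilon", "sse", "converged"],
        "properties": {
          "width_cm": {"type": "number", "exclusiveMinimum": 0},
          "n_intervals": {"type": "integer", "minimum": 0},
          "mean_interval_s": {"type": "number", "minimum": 0},
          "Q": {"type": "number", "minimum": 0},
          "alpha": {"type": ["number", "null"]},
          "beta": {"type": ["number", "null"]},
          "epsilon": {"type": ["number", "null"]},
          "sse": {"type": ["number", "null"]},
          "converged": {"type": "boolean"}
        }
      }
    },
    "beta_trend": {
      "type": ["object", "null"],
      "required": ["slope", "intercept", "r_squared"],
      "properties": {
        "slope": {"type": "number"},
        "intercept": {"type": "number"},
        "r_squared": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "groups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["width_cm", "trial_id", "group_index", "S",
                     "t1_s", "tN_s", "tS_s", "QS"],
        "properties": {
          "width_cm": {"type": "number"},
          "trial_id": {"type": "string"},
          "group_index": {"type": "integer", "minimum": 1},
          "S": {"type": "integer", "minimum": 2},
          "t1_s": {"type": "number", "minimum": 0},
          "tN_s": {"type": "number", "minimum": 0},
          "tS_s": {"type": "number", "exclusiveMinimum": 0},
          "QS": {"type": "number", "exclusiveMinimum": 0}
        }
      }
    },
    "group_summary": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["width_cm", "n_groups", "min_size", "mean_QS", "Q"],
        "properties": {
          "width_cm": {"type": "number"},
          "n_groups": {"type": "integer", "minimum": 0},
          "min_size": {"type": "integer", "minimum": 2},
          "mean_QS": {"type": ["number", "null"]},
          "Q": {"type": "number"}
        }
      }
    },
    "n_singular_groups": {"type": "integer", "minimum": 0},
    "correlations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["width_cm", "r", "p_two_tailed", "n"],
        "properties": {
          "width_cm": {"type": "number"},
          "r": {"type": "number", "minimum": -1, "maximum": 1},
          "p_two_tailed": {"type": "number", "minimum": 0, "maximum": 1},
          "n": {"type": "integer", "minimum": 3}
        }
      }
    },
    "pairwise_tests": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["width_a", "width_b", "statistic", "p", "stars"],
        "properties": {
          "width_a": {"type": "number"},
          "width_b": {"type": "number"},
          "statistic": {"type": "number"},
          "p": {"type": "number", "minimum": 0, "maximum": 1},
          "p_adjusted": {"type": "number", "minimum": 0, "maximum": 1},
          "stars": {"type": "integer", "minimum": 0, "maximum": 3},
          "n_a": {"type": "integer"},
          "n_b": {"type": "integer"}
        }
      }
    },
    "control_tests": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["width_cm", "statistic", "p_two_tailed", "stars"],
        "properties": {
          "width_cm": {"type": "number"},
          "statistic": {"type": "number"},
          "p_two_tailed": {"type": "number", "minimum": 0, "maximum": 1},
          "stars": {"type": "integer", "minimum": 0, "maximum": 3},
          "n_repellent": {"type": "integer"},
          "n_control": {"type": "integer"}
        }
      }
    },
    "provenance": {
      "type": "object",
      "required": ["source", "n_trials", "options", "schema_version"],
      "properties": {
        "source": {"type": "string"},
        "n_trials": {"type": "integer", "minimum": 1},
        "options": {"type": "object"},
        "thresholds_s": {"type": "object"},
        "schema_version": {"type": "string"},
        "timestamp": {"type": "string"}
      }
    }
  }
}
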