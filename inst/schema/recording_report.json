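{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "avalanchr recording report",
  "type": "object",
  "required": ["n_neurons", "frame_interval_s", "states"],
  "properties": {
    "n_neurons": {"type": "integer", "minimum": 1},
    "frame_interval_s": {"type": "number", "exclusiveMinimum": 0},
    "states": {
      "type": "object",
      "required": ["up", "down"],
      "required_per_state": ["family", "n_avalanches"],
      "properties": {
        "up": {"$ref": "#/$defs/state"},
        "down": {"$ref": "#/$defs/state"}
      }
    },
    "state_durations": {
      "type": "object",
      "properties": {
        "t_up_mean": {"type": ["number", "null"]},
        "t_down_mean": {"type": ["number", "null"]},
        "n_up": {"type": "integer"},
        "n_down": {"type": "integer"}
      }
    },
    "isi_s": {
      "type": "object",
      "properties": {
        "up": {"type": ["number", "null"]},
        "down": {"type": ["number", "null"]}
      }
    }
  },
  "$defs": {
    "state": {
      "type": "object",
      "required": ["family", "n_avalanches"],
      "properties": {
        "family": {"enum": ["power_law", "exponential_like", "none"]},
        "n_avalanches": {"type": "integer", "minimum": 0},
        "tau": {"type": ["number", "null"]},
        "tau_unc": {"type": ["number", "null"]},
        "alpha": {"type": ["number", "null"]},
        "alpha_unc": {"type": ["number", "null"]},
        "beta_S": {"type": ["number", "null"]},
        "beta_S_unc": {"type": ["number", "null"]},
        "beta_T": {"type": ["number", "null"]},
        "beta_T_unc": {"type": ["number", "null"]},
        "gamma": {"type": ["number", "null"]},
        "gamma_unc": {"type": ["number", "null"]},
        "p_size": {"type": "object"},
        "p_duration": {"type": "object"},
        "scaling_relation_residual": {"type": ["number", "null"]},
        "scaling_relation_pass": {"type": "boolean"},
        "beta_relation_residual": {"type": ["number", "null"]},
        "beta_relation_pass": {"type": "boolean"}
      }
    }
  }
}
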