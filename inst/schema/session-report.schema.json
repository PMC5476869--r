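{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "mindmotion session report",
  "type": "object",
  "required": ["segments", "comparisons", "excluded", "provenance"],
  "properties": {
    "segments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["participant", "session", "segment", "range_yaw",
                     "range_pitch", "range_roll", "curve_area", "duration"],
        "properties": {
          "participant": {"type": "string"},
          "session": {"type": "integer"},
          "segment": {"type": "string"},
          "range_yaw": {"type": "number", "minimum": 0},
          "range_pitch": {"type": "number", "minimum": 0},
          "range_roll": {"type": "number", "minimum": 0},
          "curve_area": {"type": "number", "minimum": 0},
          "duration": {"type": "number", "exclusiveMinimum": 0}
        }
      }
    },
    "comparisons": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["level", "id", "group", "segment", "session_a", "session_b",
                     "area_before", "area_after", "percent_change", "f_cut",
                     "power_a", "power_b", "power_ratio", "verdict"],
        "properties": {
          "level": {"enum": ["participant", "group"]},
          "verdict": {"enum": ["reduced", "increased", "negligible"]},
          "f_cut": {"type": "number", "exclusiveMinimum": 0},
          "power_a": {"type": "number", "minimum": 0},
          "power_b": {"type": "number", "minimum": 0}
        }
      }
    },
    "scores": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["group", "scale", "timepoint", "n", "mean", "mean_rounded"]
      }
    },
    "excluded": {"type": "array", "items": {"type": "string"}},
    "provenance": {
      "type": "object",
      "required": ["package", "version", "config_hash"],
      "properties": {
        "package": {"const": "mindmotion"},
        "version": {"type": "string"},
        "config_hash": {"type": "string"}
      }
    }
  }
}
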