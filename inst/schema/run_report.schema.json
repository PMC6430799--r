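{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "chiralseq run report",
  "description": "Machine-readable report of a chiralseq evaluation workflow. Reports are pure functions of (inputs, config, seed): every number is recomputable from the stored inputs and seeds.",
  "type": "object",
  "required": ["tool", "version", "workflow", "seed", "config", "stages"],
  "properties": {
    "tool": { "const": "chiralseq" },
    "version": { "type": "string" },
    "workflow": { "enum": ["germline_eval", "somatic_eval"] },
    "seed": { "type": "integer" },
    "config": { "type": "object" },
    "stages": {
      "type": "object",
      "minProperties": 1,
      "properties": {
        "partition": {
          "type": "object",
          "properties": {
            "counts": { "type": "object" },
            "cross_alignment": { "type": ["array", "null"] }
          }
        },
        "downsample": {
          "type": "object",
          "properties": {
            "fraction": { "type": "number" },
            "human_cov": { "type": "number" },
            "chiral_cov": { "type": "number" }
          }
        },
        "evaluation": {
          "type": "object",
          "properties": {
            "expected": { "type": "integer" },
            "detected": { "type": "integer" },
            "sensitivity": { "type": "number" },
            "n_tp": { "type": "integer" },
            "n_fp": { "type": "integer" },
            "vaf_regression": { "type": ["object", "null"] }
          }
        },
        "optimize": {
          "type": "object",
          "properties": {
            "thresholds": { "type": "object" },
            "n_tp_retained": { "type": "integer" },
            "n_fp_retained": { "const": 0 }
          }
        },
        "filter": {
          "type": "object",
          "properties": {
            "n_sample": { "type": "integer" },
            "n_sample_retained": { "type": "integer" }
          }
        }
      }
    }
  }
}
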