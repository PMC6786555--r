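{
  "type": "object",
  "required": ["tool", "version", "seed", "parameters", "samples"],
  "properties": {
    "tool": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "parameters": {
      "type": "object",
      "required": ["span", "keep_fraction", "top_fraction", "alpha",
                   "pval_method", "stages"],
      "properties": {
        "span": {"type": "number"},
        "iterations": {"type": "integer"},
        "keep_fraction": {"type": "number"},
        "top_fraction": {"type": "number"},
        "alpha": {"type": "number"},
        "pval_method": {"type": "string"},
        "stages": {"type": "array", "items": {"type": "string"}}
      }
    },
    "samples": {
      "type": "object",
      "required": ["n_samples", "n_donors", "platforms"],
      "properties": {
        "n_samples": {"type": "integer"},
        "n_donors": {"type": "integer"},
        "n_probes": {"type": "integer"},
        "platforms": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["platform", "n_samples"],
            "properties": {
              "platform": {"type": "string"},
              "n_samples": {"type": "integer"}
            }
          }
        }
      }
    },
    "concordance": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["platform", "mean_within_donor_correlation",
                     "mean_across_donor_correlation", "sn_ratio",
                     "n_within_pairs", "n_across_pairs"],
        "properties": {
          "platform": {"type": "string"},
          "mean_within_donor_correlation": {"type": "number"},
          "mean_across_donor_correlation": {"type": "number"},
          "sn_ratio": {"type": "number"},
          "n_within_pairs": {"type": "integer"},
          "n_across_pairs": {"type": "integer"}
        }
      }
    },
    "pca": {
      "type": "object",
      "required": ["n_components", "explained_variance"],
      "properties": {
        "n_components": {"type": "integer"},
        "explained_variance": {"type": "array", "items": {"type": "number"}}
      }
    },
    "property_correlations": {
      "type": "object",
      "required": ["n_rows", "n_significant", "var_gc"],
      "properties": {
        "n_rows": {"type": "integer"},
        "n_significant": {"type": "integer"},
        "var_gc": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["platform", "r"],
            "properties": {
              "platform": {"type": "string"},
              "r": {"type": "number"},
              "p": {"type": "number"}
            }
          }
        }
      }
    },
    "enrichment": {
      "type": "object",
      "required": ["n_gene_sets", "top_variance"],
      "properties": {
        "n_gene_sets": {"type": "integer"},
        "top_variance": {"type": "array"}
      }
    }
  }
}
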