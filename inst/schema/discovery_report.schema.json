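{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "opalscan discovery report",
  "type": "object",
  "required": ["config", "inputs", "scan", "n_candidates", "candidates"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["min_orf_len", "d4_min", "delta_min", "min_merged_pairs",
                   "k_min", "rho_min", "alpha", "n_permutations", "seed"]
    },
    "inputs": {
      "type": "object",
      "required": ["contigs", "n_contigs"]
    },
    "scan": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["contig_id", "length", "gc", "evaluable", "candidate"]
      }
    },
    "n_candidates": {"type": "integer", "minimum": 0},
    "candidates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["contig_id", "recoding", "circularity", "genome_stats"],
        "properties": {
          "recoding": {
            "type": "object",
            "required": ["length", "gc", "d11", "d4", "delta",
                         "merged_pairs"]
          },
          "circularity": {
            "type": "object",
            "required": ["overlap_len", "is_circular", "trimmed_length"]
          },
          "genome_stats": {
            "type": "object",
            "required": ["genome_length", "gc", "density_all",
                         "density_cds", "pI_mean"]
          }
        }
      }
    }
  }
}
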