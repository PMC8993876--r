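{
  "version": "reconstructed-v1",
  "system": "M-IPSS-R",
  "comment": "Mutation-augmented score over four factors: distinct selected-gene mutation count, marrow morphology (dysplasia bins below 5% blasts, blast bins at or above), cytogenetic category, and age.",
  "selected_genes": ["TET2", "ASXL1", "TP53", "RUNX1", "NRAS", "KRAS", "NOTCH1"],
  "factors": {
    "gene_mutations": {
      "kind": "count",
      "points": {"0": 0, "1": 1, "2": 2, "3": 3, "4": 4, "gt4": 5}
    },
    "morphology": {
      "kind": "morphology",
      "dysplasia_points": {"SLD": 0, "MLD": 1},
      "blast_bins": [
        {"lo": 5, "hi": 10, "lo_incl": true, "hi_incl": true, "points": 2},
        {"lo": 10, "hi": null, "lo_incl": false, "hi_incl": false, "points": 3}
      ]
    },
    "cytogenetics": {
      "kind": "categorical",
      "points": {"VeryGood": 0, "Good": 0, "Intermediate": 1, "Poor": 2, "VeryPoor": 3}
    },
    "age": {
      "kind": "bins",
      "bins": [
        {"lo": 0, "hi": 30, "lo_incl": true, "hi_incl": true, "points": 0},
        {"lo": 30, "hi": 50, "lo_incl": false, "hi_incl": true, "points": 0.5},
        {"lo": 50, "hi": 60, "lo_incl": false, "hi_incl": true, "points": 1},
        {"lo": 60, "hi": null, "lo_incl": false, "hi_incl": false, "points": 2}
      ]
    }
  },
  "tiers": {
    "comment": "total <= 3 Low; 3.5-5.5 Intermediate; > 5.5 High (totals below 1.5 classified Low)",
    "cuts": [3, 5.5],
    "labels": ["Low", "Intermediate", "High"]
  }
}
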