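{
  "version": "ipssr-v1",
  "system": "IPSS-R",
  "comment": "Revised International Prognostic Scoring System component points. Numeric factors are half-open bins over [0, Inf); cytogenetics is categorical.",
  "factors": {
    "cytogenetics": {
      "kind": "categorical",
      "points": {"VeryGood": 0, "Good": 1, "Intermediate": 2, "Poor": 3, "VeryPoor": 4}
    },
    "bm_blast_pct": {
      "kind": "bins",
      "bins": [
        {"lo": 0, "hi": 2, "lo_incl": true, "hi_incl": true, "points": 0},
        {"lo": 2, "hi": 5, "lo_incl": false, "hi_incl": false, "points": 1},
        {"lo": 5, "hi": 10, "lo_incl": true, "hi_incl": true, "points": 2},
        {"lo": 10, "hi": null, "lo_incl": false, "hi_incl": false, "points": 3}
      ]
    },
    "hemoglobin": {
      "kind": "bins",
      "bins": [
        {"lo": 0, "hi": 8, "lo_incl": true, "hi_incl": false, "points": 1.5},
        {"lo": 8, "hi": 10, "lo_incl": true, "hi_incl": false, "points": 1},
        {"lo": 10, "hi": null, "lo_incl": true, "hi_incl": false, "points": 0}
      ]
    },
    "platelets": {
      "kind": "bins",
      "bins": [
        {"lo": 0, "hi": 50, "lo_incl": true, "hi_incl": false, "points": 1},
        {"lo": 50, "hi": 100, "lo_incl": true, "hi_incl": false, "points": 0.5},
        {"lo": 100, "hi": null, "lo_incl": true, "hi_incl": false, "points": 0}
      ]
    },
    "anc": {
      "kind": "bins",
      "bins": [
        {"lo": 0, "hi": 0.8, "lo_incl": true, "hi_incl": false, "points": 0.5},
        {"lo": 0.8, "hi": null, "lo_incl": true, "hi_incl": false, "points": 0}
      ]
    }
  },
  "tiers": {
    "comment": "five-tier cutpoints, total <= cut maps to the tier",
    "cuts": [1.5, 3, 4.5, 6],
    "labels": ["VeryLow", "Low", "Intermediate", "High", "VeryHigh"],
    "collapse4": {"VeryLow": "Low"}
  }
}
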