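{
  "version": "ipssr-comprehensive-v1",
  "comment": "IPSS-R comprehensive cytogenetic risk categories; rules applied in order, first match wins. Lesion specs match normalized arm-level tokens.",
  "rules": [
    {"id": "very_complex_gt3", "category": "VeryPoor", "points": 4,
     "when": {"kind": "complex", "min_abnormalities": 4}},
    {"id": "complex_eq3", "category": "Poor", "points": 3,
     "when": {"kind": "complex", "min_abnormalities": 3, "max_abnormalities": 3}},
    {"id": "poor_chr3q", "category": "Poor", "points": 3,
     "when": {"kind": "contains_any", "max_n": 2, "lesions": [
       {"type": "inv", "chrom": "3"},
       {"type": "t", "chrom": "3", "arm": "q"},
       {"type": "del", "chrom": "3", "arm": "q"}]}},
    {"id": "poor_monosomy7", "category": "Poor", "points": 3,
     "when": {"kind": "contains_any", "max_n": 2, "lesions": [
       {"type": "loss", "chrom": "7"}]}},
    {"id": "poor_double_incl_del7q", "category": "Poor", "points": 3,
     "when": {"kind": "double_including", "lesions": [
       {"type": "del", "chrom": "7", "arm": "q"}]}},
    {"id": "verygood_isolated", "category": "VeryGood", "points": 0,
     "when": {"kind": "isolated_any", "lesions": [
       {"type": "loss", "chrom": "Y"},
       {"type": "del", "chrom": "11", "arm": "q"}]}},
    {"id": "good_normal", "category": "Good", "points": 1,
     "when": {"kind": "normal"}},
    {"id": "good_isolated", "category": "Good", "points": 1,
     "when": {"kind": "isolated_any", "lesions": [
       {"type": "del", "chrom": "5", "arm": "q"},
       {"type": "del", "chrom": "12", "arm": "p"},
       {"type": "del", "chrom": "20", "arm": "q"}]}},
    {"id": "good_double_incl_del5q", "category": "Good", "points": 1,
     "when": {"kind": "double_including", "lesions": [
       {"type": "del", "chrom": "5", "arm": "q"}]}},
    {"id": "intermediate_isolated", "category": "Intermediate", "points": 2,
     "when": {"kind": "isolated_any", "lesions": [
       {"type": "del", "chrom": "7", "arm": "q"},
       {"type": "gain", "chrom": "8"},
       {"type": "gain", "chrom": "19"},
       {"type": "i", "chrom": "17", "arm": "q"}]}},
    {"id": "intermediate_residual", "category": "Intermediate", "points": 2,
     "when": {"kind": "single_or_double"}}
  ]
}
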