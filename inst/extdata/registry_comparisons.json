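[
  {
    "name": "prior_ablation_paf_vs_peaf",
    "test": "two_prop_z",
    "k1": 2, "n1": 9, "k2": 13, "n2": 16,
    "printed_p": 0.002, "core": true,
    "note": "history of prior ablation, PAF vs PeAF/LS-PeAF"
  },
  {
    "name": "cardioversion_paf_vs_peaf",
    "test": "two_prop_z",
    "k1": 2, "n1": 9, "k2": 12, "n2": 16,
    "printed_p": 0.005, "core": true,
    "note": "history of cardioversion, PAF vs PeAF/LS-PeAF"
  },
  {
    "name": "sources_per_patient_paf_vs_peaf",
    "test": "t_from_summary",
    "m1": 0.9, "sd1": 1.2, "n1": 9, "m2": 2.2, "sd2": 1.3, "n2": 16,
    "printed_p": 0.011, "core": true,
    "note": "EGF-identified sources per patient, PAF vs PeAF/LS-PeAF"
  },
  {
    "name": "per_protocol_paf_vs_peaf",
    "test": "two_prop_z",
    "k1": 7, "n1": 9, "k2": 5, "n2": 16,
    "printed_p": 0.013, "core": true,
    "note": "treated per protocol, PAF vs PeAF/LS-PeAF"
  },
  {
    "name": "ffaf_denovo_vs_redo",
    "test": "two_prop_z",
    "k1": 11, "n1": 13, "k2": 2, "n2": 8,
    "printed_p": 0.003, "core": true,
    "note": "freedom from AF, de novo vs redo procedures"
  },
  {
    "name": "ffaf_high_vs_low_egfc",
    "test": "two_prop_z",
    "k1": 9, "n1": 10, "k2": 5, "n2": 11,
    "printed_p": 0.015, "core": true,
    "note": "freedom from AF, above- vs below-median EGFC"
  },
  {
    "name": "type1_paf_vs_peaf",
    "test": "two_prop_z",
    "k1": 3, "n1": 9, "k2": 1, "n2": 16,
    "printed_p": 0.038, "core": true,
    "note": "Type I phenotype frequency, PAF vs PeAF/LS-PeAF"
  },
  {
    "name": "ffaf_peaf_denovo_vs_redo",
    "test": "two_prop_z",
    "k1": 6, "n1": 8, "k2": 1, "n2": 5,
    "printed_p": 0.026, "core": false,
    "note": "freedom from AF, de novo vs redo among PeAF/LS-PeAF"
  },
  {
    "name": "ffaf_paf_vs_peaf",
    "test": "two_prop_z",
    "k1": 6, "n1": 8, "k2": 6, "n2": 13,
    "printed_p": 0.10, "core": false,
    "note": "freedom from AF, PAF vs PeAF/LS-PeAF (not significant)"
  },
  {
    "name": "ffaf_paf_denovo_vs_redo",
    "test": "two_prop_z",
    "k1": 5, "n1": 5, "k2": 1, "n2": 3,
    "printed_p": 0.017, "core": false,
    "note": "printed_discrepancy: recomputes to 0.018 under the pooled one-tailed z; the original test for this comparison is unclear"
  }
]
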