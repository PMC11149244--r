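{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ckdlabscan stage summary",
  "description": "Shape of summary.json written by run_pipeline(); numbers are serialised at 6 significant digits with alphabetical key order.",
  "type": "object",
  "required": [
    "a3_pct_by_stage_paired",
    "ckd_pct_among_paired",
    "cross_tab",
    "diabetes_pct_by_ckd",
    "mean_age_by_ckd",
    "n_ckd_paired",
    "n_indexed",
    "n_paired",
    "n_unpaired",
    "pairing_pct_by_stage",
    "specialty_pct",
    "stage_share_among_ckd",
    "unpaired_pct"
  ],
  "properties": {
    "n_indexed": {"type": "integer", "minimum": 0},
    "n_paired": {"type": "integer", "minimum": 0},
    "n_unpaired": {"type": "integer", "minimum": 0},
    "n_ckd_paired": {"type": "integer", "minimum": 0},
    "unpaired_pct": {"type": "number", "minimum": 0, "maximum": 100},
    "ckd_pct_among_paired": {"type": "number", "minimum": 0, "maximum": 100},
    "stage_share_among_ckd": {"type": "object"},
    "pairing_pct_by_stage": {"type": "object"},
    "a3_pct_by_stage_paired": {"type": "object"},
    "mean_age_by_ckd": {"type": "object"},
    "diabetes_pct_by_ckd": {"type": "object"},
    "specialty_pct": {"type": "object"},
    "specialty_pct_by_stage": {"type": "object"},
    "km_ci_6mo_pct_by_stage": {"type": "object"},
    "cross_tab": {"type": "object"}
  }
}
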