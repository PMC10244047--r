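# Pooled eligibility criteria of the acetylcholinesterase-inhibitor trials:
# a cohort subject is trial eligible iff every criterion holds.
criteria:
  - field: age_years
    op: range
    args: [40, 94]
  - field: baseline_score
    op: range
    args: [10, 26]
  - field: diagnosis_code
    op: in_set
    args: [alzheimers, alzheimers_cvd]
  - field: has_caregiver
    op: equals
    args: true
  - field: has_other_major_psychiatric_disorder
    op: equals
    args: false
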