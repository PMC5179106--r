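# Free-text development-stage labels (lower-cased before lookup) mapped
# onto the canonical three-token vocabulary. Extend by passing your own
# file to stage_synonyms(). Anything unmapped falls back to
# "experimental" with a warning.
approved:
  - approved
  - fda approved
  - launched
  - marketed
  - registered
clinical_trial:
  - clinical trial
  - clinical trials
  - in clinical trial
  - phase 1
  - phase 2
  - phase 3
  - phase 4
  - phase i
  - phase ii
  - phase iii
  - phase iv
  - phase i/ii
  - phase ii/iii
  - phase 1/2
  - phase 2/3
  - investigational
experimental:
  - experimental
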