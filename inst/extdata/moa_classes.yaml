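# Mode-of-action vocabulary, partitioned by the direction of the drug's
# effect on its target. "inhibiting" modes are mechanistically compatible
# with gain-of-function disease roles, "activating" modes with
# loss-of-function roles; "neutral" modes make no directional claim and
# always yield an "unknown" compatibility call.
inhibiting:
  - inhibitor
  - antagonist
  - antibody
  - blocker
  - suppressor
activating:
  - agonist
  - activator
  - inducer
  - stimulator
neutral:
  - substrate
  - modulator
  - binder
  - cofactor
  - unknown
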