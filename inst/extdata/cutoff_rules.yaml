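# Binary effect/neutral cutoff rules, one per prediction method.
# orientation: greater_is_effect (score above threshold = effect) or
#              less_is_effect (score below threshold = effect).
synpred:
  threshold: 0.5
  orientation: greater_is_effect
snap2:
  threshold: 0
  orientation: greater_is_effect
polyphen2:
  threshold: 0.5
  orientation: greater_is_effect
sift:
  threshold: 0.05
  orientation: less_is_effect
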