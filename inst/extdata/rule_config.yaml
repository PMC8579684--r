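keywords:
  '1':
  - observ*
  - reassess*
  - review*
  - demonstrat*
  - check*
  - educat*
  - teach*
  - taught
  - explain*
  - reinforce*
  - discuss*
  - instruction
  - constraints
  - how to use
  '2':
  - inhaler
  - MDI
  - neb
  - nebulizer
  - optichamber
  - spacer
  '3':
  - techniques
  - administrations
  - dosing
  - guidance
  '4':
  - asthma/rescue/daily/preventive/control medication
  - ICS
  - list of maintenance and rescue medications
rules:
  a:
  - 1
  - 2
  b:
  - 1
  - 3
  - 4
strict_plural: no
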