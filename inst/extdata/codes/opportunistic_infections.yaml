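# ICD-9-CM code sets for the six opportunistic-infection flags.
pjp:
  - "136.3"
cmv:
  - "078.5"
  - "484.1"
tuberculosis:
  - 010-012
  - "018"
candidiasis:
  - "112.4"
  - "112.84"
cryptococcosis:
  - "117.5"
  - "321.0"
mac:
  - "031.2"
  - "031.9"
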