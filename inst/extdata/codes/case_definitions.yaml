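# ICD-9-CM case-definition code sets. Patterns are prefixes ("013",
# "054.3") or inclusive 3-digit rubric ranges ("042-044").
hiv:
  - 042-044
cns_infection:
  - "013"
  - "047"
  - "053"
  - "094"
  - "200"
  - "320"
  - "321"
  - "322"
  - "323"
  - "054.3"
  - "054.4"
  - "114.2"
  - "130.0"
  - "321.0"
  - "003.21"
  - "098.82"
  - "112.83"
  - "115.91"
cognitive:
  - "290"
  - "293"
  - "294"
  - "332"
  - "345"
  - "348.1"
  - "348.3"
  - "780.3"
vasculopathy:
  - "325"
  - "430"
  - "431"
  - "432"
  - "433"
  - "434"
  - "435"
  - "436"
  - "437"
peripheral_neuropathy:
  - "350"
  - "351"
  - "353"
  - "354"
  - "355"
  - "356"
  - "357"
  - "358"
malignancy:
  - 140-208
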