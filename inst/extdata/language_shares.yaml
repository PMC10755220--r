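# Native-speaker shares (raw published percentages) for the multilingual
# countries; monolingual countries need no entry (weight 1 implied).
# Shares need not sum to 100: residuals speak no official language natively.
BE:
  nl: 59
  fr: 40
  de: 1
CY:
  el: 81
  tr: 1
FI:
  fi: 87
  sv: 5
IE:
  en: 93
  ga: 3
LU:
  fr: 56
  lb: 20
  de: 6
MT:
  mt: 86
  en: 12
CH:
  de: 62.8
  fr: 22.9
  it: 8.2
  rm: 0.5
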