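country,term,measure,status
AT,anxiety,teleworking recommendations,significant
BE,anxiety,teleworking recommendations,significant
HR,anxiety,teleworking recommendations,significant
FR,anxiety,teleworking recommendations,significant
DE,anxiety,teleworking recommendations,significant
GR,anxiety,teleworking recommendations,significant
IE,anxiety,teleworking recommendations,significant
IT,anxiety,teleworking recommendations,significant
LU,anxiety,teleworking recommendations,significant
MT,anxiety,teleworking recommendations,significant
NO,anxiety,teleworking recommendations,significant
PL,anxiety,teleworking recommendations,significant
PT,anxiety,teleworking recommendations,significant
RO,anxiety,teleworking recommendations,significant
SI,anxiety,teleworking recommendations,significant
ES,anxiety,teleworking recommendations,significant
CH,anxiety,teleworking recommendations,significant
BG,anxiety,teleworking recommendations,not_significant
CZ,anxiety,teleworking recommendations,not_significant
DK,anxiety,teleworking recommendations,not_significant
FI,anxiety,teleworking recommendations,not_significant
LV,anxiety,teleworking recommendations,not_significant
LT,anxiety,teleworking recommendations,not_significant
NL,anxiety,teleworking recommendations,not_significant
SK,anxiety,teleworking recommendations,not_significant
SE,anxiety,teleworking recommendations,not_significant
GB,anxiety,teleworking recommendations,not_significant
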