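country,name,population
AT,Austria,8901064
BE,Belgium,11522440
BG,Bulgaria,6951482
HR,Croatia,4058165
CY,Cyprus,888005
CZ,Czechia,10693939
DK,Denmark,5822763
EE,Estonia,1328976
FI,Finland,5525292
FR,France,67320216
DE,Germany,83166711
GR,Greece,10718565
HU,Hungary,9769526
IS,Iceland,364134
IE,Ireland,4964440
IT,Italy,59641488
LV,Latvia,1907675
LI,Liechtenstein,38747
LT,Lithuania,2794090
LU,Luxembourg,626108
MT,Malta,514564
NL,Netherlands,17407585
NO,Norway,5367580
PL,Poland,37958138
PT,Portugal,10295909
RO,Romania,19328838
SK,Slovakia,5457873
SI,Slovenia,2095861
ES,Spain,47332614
SE,Sweden,10327589
CH,Switzerland,8606033
GB,United Kingdom,66647112
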