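country_code,group
USA,high
CAN,high
GBR,high
FRA,high
DEU,high
ITA,high
ESP,high
PRT,high
GRC,high
IRL,high
NOR,high
SWE,high
FIN,high
DNK,high
NLD,high
BEL,high
CHE,high
AUT,high
JPN,high
KOR,high
AUS,high
NZL,high
ISR,high
POL,high
CZE,high
HUN,high
BRA,middle
ZAF,middle
MEX,middle
CHL,middle
ARG,middle
PER,middle
COL,middle
CRI,middle
CUB,middle
HND,middle
GTM,middle
ECU,middle
BOL,middle
VEN,middle
JAM,middle
RUS,middle
TUR,middle
IRN,middle
ROU,middle
CHN,middle
THA,middle
IND,middle
IDN,middle
PHL,middle
VNM,middle
MAR,middle
TUN,middle
EGY,middle
BWA,middle
NAM,middle
SWZ,middle
CMR,middle
NGA,middle
GHA,middle
LSO,middle
PAK,middle
UGA,low
KEN,low
TZA,low
MWI,low
MOZ,low
ETH,low
ZWE,low
ZMB,low
SEN,low
MLI,low
NER,low
TGO,low
BEN,low
GMB,low
GIN,low
BFA,low
CIV,low
COD,low
CAF,low
RWA,low
BDI,low
MDG,low
HTI,low
KHM,low
NPL,low
BGD,low
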