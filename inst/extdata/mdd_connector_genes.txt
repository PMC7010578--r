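ALB
APP
CHPF
CNIH4
DLG4
GALR2
GHRL
GNAQ
GPRASP1
GRB2
GRIK2
HIST1H2AL
HLF
HSP90AB1
MAX
MEF2C
PDZD3
PPP1CA
PPP1R16A
PPP2R2A
PRKACA
PRKCA
PRNP
PTPN11
SHTN1
SMAD9
SP1
SPINT2
SPP1
STX1A
SYT1
TCF4
TCL1A
TGFBR1
TNFRSF14
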