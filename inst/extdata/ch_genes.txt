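# Genes recurrently mutated in clonal hematopoiesis (default panel; replace
# with the panel-specific list as needed, one symbol per line)
DNMT3A
TET2
ASXL1
PPM1D
TP53
ATM
CHEK2
JAK2
SF3B1
SRSF2
U2AF1
GNB1
IDH1
IDH2
CBL
KRAS
NRAS
GNAS
BCOR
BCORL1
STAG2
EZH2
RUNX1
CEBPA
SETDB1
ZNF318
YLPM1
SRCAP
MYD88
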