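# Homologous-recombination pathway genes (default panel stand-in; replace
# with the panel-specific list as needed, one symbol per line)
BRCA1
BRCA2
PALB2
BARD1
BRIP1
RAD51
RAD51B
RAD51C
RAD51D
RAD54L
NBN
MRE11
RAD50
ATR
ATM
CHEK1
CHEK2
CDK12
FANCA
FANCC
FANCD2
FANCE
FANCF
FANCI
FANCL
FANCM
XRCC2
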