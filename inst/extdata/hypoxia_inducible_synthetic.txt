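# Synthetic stand-in exclusion list of hypoxia-inducible genes.
# Representative set: genes reported as hypoxia-regulated in hADSC plus
# canonical HIF-1 target genes. Not the full curated list of 114 genes;
# users should supply their own list for production screens.
VEGFA
PGK1
GAPDH
TFRC
CA9
SLC2A1
LDHA
PDK1
BNIP3
ADM
ENO1
ALDOA
HK2
PFKFB3
EGLN3
NDRG1
P4HA1
ANKRD37
DDIT4
EPO
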