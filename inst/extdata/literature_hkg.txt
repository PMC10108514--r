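# Literature-reported housekeeping gene candidates for hypoxia studies.
# The 15 symbols screened against the RNA-seq panel, plus the additional
# candidates that reached the top-8 screen table (CHFR, GGA1, NONO).
ACTB
ALAS1
B2M
GAPDH
GUSB
HPRT1
PGK1
POLR2B
PPIA
RPL13A
RPLP0
RRP1
TBP
TFRC
YWHAZ
CHFR
GGA1
NONO
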