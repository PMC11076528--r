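# CHIP-associated driver genes: somatic variants annotated to these genes
# are excluded from passenger counting; carriers of driver mutations in
# them are excluded from the scored cohort. One symbol per line.
DNMT3A
ASXL1
TET2
JAK2
SF3B1
TP53
PPM1D
SRSF2
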