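# Per-aspect protein pairs selected by predicted-GO similarity (per-protein
# precision >= 0.75, >= 70% shared positive terms) and the subset matched in
# the STRING interaction table at confidence >= 70, from the published
# CAFA5 analysis.
aspect,pairs_selected,pairs_matched
BP,179,141
MF,216,153
CC,183,109
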