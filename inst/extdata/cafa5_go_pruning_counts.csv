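# Per-aspect GO term counts on CAFA5 before pruning and the number pruned
# at the default annotation-frequency threshold of 21.
aspect,total_terms,pruned_terms
BP,21285,13641
MF,7224,5740
CC,2957,1932
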