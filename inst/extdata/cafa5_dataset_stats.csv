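# CAFA5 cohort-level constants used for documented reference behavior.
name,value
n_proteins,142246
n_go_terms,31466
n_species,3156
n_train,128020
n_test,14225
pruning_frequency,21
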