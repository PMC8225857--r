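file	sample_id	mouse_id	subset	genotype
toy_clonotypes.tsv	toy_s1	toy_m1	CD4SP	control
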