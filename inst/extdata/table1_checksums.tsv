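file	md5
table1_features.tsv	aba128dba00fc3cb9ba68d6306fefa7c
table1_fragments.tsv	56b25cdaaf2ecce1ad86f71812f1ee5b
table1_ms2.mgf	183c3d94c60bce4fc3ed56a25e05e637
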