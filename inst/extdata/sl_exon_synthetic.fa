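>SL_exon_synthetic_24mer synthetic stand-in; the real leader is a user input
ACGCTATATAAGTACAGTTTCTGG
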