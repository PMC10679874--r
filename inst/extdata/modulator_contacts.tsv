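# Structure-defined splicing-modulator contact residues (1-based positions
# on the ungapped human reference sequences). Only the residues named in
# print are shipped; the remaining SF3B1-PB contacts are user-extensible.
modulator	protein	position	residue
PB	SF3B1	1078	V
PB	PHF5A	36	C
OTS964	CDK11	572	H
OTS964	CDK11	579	G
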