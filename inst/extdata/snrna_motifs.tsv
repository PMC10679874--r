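# Example snRNA motif configuration (IUPAC patterns, optional 1-based match
# start windows). Consensi are configuration, not asserted organism truth:
# the source shows motifs only graphically.
motif_name	pattern	window_start	window_end
Sm site	RAUUUUUGR	NA	NA
LSm site	UUUU	80	120
branch-point interaction	GUAGUA	25	55
5'SS interaction	ACAGAGA	30	60
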