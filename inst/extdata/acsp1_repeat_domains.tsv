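# BED-like domain annotation for an aciniform spidroin repeat unit, amino
# acid coordinates (0-based half-open), label in column 4. Ranges follow
# the published NMR-based secondary-structure description of the repeat:
# a helix-rich domain over the first 150 residues (with the major helical
# region spanning residues 102-151, 1-based) and an unstructured tail.
ref	start	end	label
repeat	0	150	helix_rich
repeat	150	199	unstructured
repeat	101	151	major_helical
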