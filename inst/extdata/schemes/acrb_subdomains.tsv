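# Curated subdomain residue ranges for E. coli AcrB (author numbering).
# These boundaries are this package's curation (editable), assembled from
# the standard porter-domain subdomain nomenclature; they are NOT ground
# truth and users should adjust them to their own structure annotations.
# core = transmembrane-domain superposition anchor.
set	start	end
core	1	32
core	336	364
core	439	555
core	871	1033
PN1	33	101
PN1	409	438
PN2	102	180
PN2	365	408
PC1	181	276
PC2	277	335
TM2	337	357
exit_seed	758	758
exit_seed	868	868
exit_seed	101	101
lys	940	940
asn	941	941
asp	407	408
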