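# Curated subdomain residue ranges for K. pneumoniae OqxB (author
# numbering, offset by roughly +3..+6 from AcrB). This package's curation
# (editable), NOT ground truth; adjust to your own annotations.
# Proton-translocation network: K946 flips towards N947 and away from the
# titratable D410/D411 in the O/O* states.
set	start	end
core	1	35
core	339	367
core	442	558
core	875	1040
PN1	36	104
PN1	412	441
PN2	105	183
PN2	368	411
PC1	184	279
PC2	280	338
TM2	340	360
exit_seed	761	761
exit_seed	871	871
exit_seed	104	104
lys	946	946
asn	947	947
asp	410	411
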