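# SYNTHETIC default per-locus Y-STR mutation rates (mutations/generation).
# These are representative values in the published per-locus magnitude
# range (1e-4 to 1e-2) for 26 single-copy loci; they are NOT an
# authoritative rate table and ship only so that simulations and examples
# run out of the box. Supply measured rates for real analyses.
locus	mu
DYS19	0.0022
DYS389I	0.0025
DYS389II	0.0035
DYS390	0.0021
DYS391	0.0026
DYS392	0.0005
DYS393	0.0011
DYS437	0.0013
DYS438	0.0004
DYS439	0.0050
DYS448	0.0014
DYS449	0.0120
DYS456	0.0042
DYS458	0.0064
DYS460	0.0057
DYS481	0.0050
DYS518	0.0100
DYS533	0.0036
DYS549	0.0055
DYS570	0.0120
DYS576	0.0140
DYS627	0.0120
DYS635	0.0040
DYS643	0.0016
DYS533B	0.0030
YGATAH4	0.0022
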