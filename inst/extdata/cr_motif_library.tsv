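# Control-region (D-loop) element library for mustelid-style mitogenomes.
# Each element is located by windowed minimum-edit-distance search; N in a
# motif matches any base at zero cost.  max_edit is the per-element edit cap;
# win_start/win_end restrict the search to a fraction of the CR span.
# source: 'published' = motif reported for mammalian/mustelid control regions;
# 'synthetic' = stand-in consensus written for this package (used by the
# bundled simulator, which plants exactly these sequences; real control
# regions will require user-supplied consensus sequences for these rows).
element	role	motif	max_edit	win_start	win_end	source
ETAS1	etas	ATGACATACATACATCTCAACTATTCTGGTCTTGGCCCCATTATTAACAGTACATATATGTA	12	0.00	0.30	synthetic
Dloop_termination	etas	GCCCCAT	0	0.00	0.30	published
TAS-A	etas	TATATGTACTATTCCTTAATCGTACAT	6	0.00	0.30	synthetic
F-box	cd_box	ATGTATATCGTGCATTAATGGCTTGCCC	6	0.10	0.35	synthetic
E-box	cd_box	AGTACATAGTACATTAAGTCGTTCATCGTACATAGC	8	0.15	0.40	synthetic
D-box	cd_box	CCTAATGGTTACAGGACATAAGTCC	5	0.20	0.45	synthetic
C-box	cd_box	TAGTACATAACATTCAATGATTGGACA	5	0.25	0.50	synthetic
B-box	cd_box	CGAGCTTAATCACCATG	3	0.30	0.55	synthetic
CSB1	csb	TTCGAATGTCCCATCGTCATGGAAC	5	0.40	0.70	synthetic
CSB2	csb	AAACCCCCCCTACCCCCG	3	0.70	0.92	synthetic
CSB3	csb	TGCCAAACCCCAAAAACAA	3	0.75	0.97	synthetic
HSP	promoter	GTCA	0	0.90	1.00	synthetic
LSP	promoter	TCGG	0	0.90	1.00	synthetic
RS3_unit	minisatellite	GCACACGTAC	2	0.50	0.85	published
ATGN9CAT	palindromic_motif	ATGNNNNNNNNNCAT	0	0.00	1.00	published
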