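# Feature table of the Mustela lutreola reference mitogenome (MW148603), 16,504 bp.
# 1-based inclusive H-strand coordinates; strand H/L; kind PCG/tRNA/rRNA/origin/control_region.
# start_codon/stop_codon as annotated at the genomic level (TA/T = incomplete stop codons
# completed by polyadenylation); aa_count excludes the termination codon.
name	kind	start	end	strand	anticodon	start_codon	stop_codon	aa_count
tRNA-Phe	tRNA	1	69	H	GAA			NA
rrnS	rRNA	70	1028	H				NA
tRNA-Val	tRNA	1029	1096	H	TAC			NA
rrnL	rRNA	1095	2665	H				NA
tRNA-Leu(UUA)	tRNA	2666	2740	H	TAA			NA
nad1	PCG	2743	3698	H		ATG	TA	318
tRNA-Ile	tRNA	3699	3767	H	GAT			NA
tRNA-Gln	tRNA	3765	3838	L	TTG			NA
tRNA-Met	tRNA	3840	3908	H	CAT			NA
nad2	PCG	3909	4950	H		ATT	T	347
tRNA-Trp	tRNA	4951	5017	H	TCA			NA
tRNA-Ala	tRNA	5028	5096	L	TGC			NA
tRNA-Asn	tRNA	5098	5170	L	GTT			NA
OL	origin	5171	5205	L				NA
tRNA-Cys	tRNA	5203	5269	L	GCA			NA
tRNA-Tyr	tRNA	5271	5338	L	GTA			NA
cox1	PCG	5340	6884	H		ATG	TAA	514
tRNA-Ser(UCA)	tRNA	6882	6950	L	TGA			NA
tRNA-Asp	tRNA	6956	7022	H	GTC			NA
cox2	PCG	7023	7706	H		ATG	TAA	227
tRNA-Lys	tRNA	7710	7776	H	TTT			NA
atp8	PCG	7778	7981	H		ATG	TAA	67
atp6	PCG	7939	8619	H		ATG	TAA	226
cox3	PCG	8619	9402	H		ATG	T	261
tRNA-Gly	tRNA	9403	9471	H	TCC			NA
nad3	PCG	9472	9818	H		ATA	TA	115
tRNA-Arg	tRNA	9819	9886	H	TCG			NA
nad4l	PCG	9887	10183	H		ATG	TAA	98
nad4	PCG	10177	11554	H		ATG	T	459
tRNA-His	tRNA	11555	11623	H	GTG			NA
tRNA-Ser(AGC)	tRNA	11624	11685	H	GCT			NA
tRNA-Leu(CUA)	tRNA	11686	11755	H	TAG			NA
nad5	PCG	11756	13576	H		ATT	TAA	606
nad6	PCG	13560	14090	L		ATG	TAA	176
tRNA-Glu	tRNA	14094	14162	L	TTC			NA
cytb	PCG	14167	15306	H		ATG	AGA	379
tRNA-Thr	tRNA	15307	15374	H	TGT			NA
tRNA-Pro	tRNA	15374	15439	L	TGG			NA
CR	control_region	15440	16504	H				NA
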