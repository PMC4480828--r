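rank	term
1	transcript_ablation
2	splice_donor_variant
3	splice_acceptor_variant
4	stop_gained
5	frameshift_variant
6	stop_lost
7	initiator_codon_variant
8	transcript_amplification
9	inframe_insertion
10	inframe_deletion
11	missense_variant
12	splice_region_variant
13	incomplete_terminal_codon_variant
14	stop_retained_variant
15	synonymous_variant
16	coding_sequence_variant
17	mature_miRNA_variant
18	5_prime_UTR_variant
19	3_prime_UTR_variant
20	non_coding_exon_variant
21	nc_transcript_variant
22	intron_variant
23	NMD_transcript_variant
24	upstream_gene_variant
25	downstream_gene_variant
26	TFBS_ablation
27	TFBS_amplification
28	TF_binding_site_variant
29	regulatory_region_ablation
30	regulatory_region_amplification
31	regulatory_region_variant
32	feature_elongation
33	feature_truncation
34	intergenic_variant
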