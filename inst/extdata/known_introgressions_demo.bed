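# Synthetic demo-scale (1:100) analogues of literature-reported wheat
# introgressions/deletions, for overlap annotation of drop calls.
chr1	0	2400000	rye_1RS_arm_translocation_analog
chr2	4000000	4850000	secondary_2BL_introgression_analog
chr2	1000000	1300000	primary_5DS_introgression_analog
chr3	3000000	4000000	deletion_1DL_analog
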