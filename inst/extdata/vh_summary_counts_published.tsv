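quantity	value
proteins_identified	798
proteins_identified_fdr01	624
protein_venn_common	745
protein_venn_exclusive_rrd	22
protein_venn_exclusive_control	31
dep_total	93
dep_up	52
dep_down	41
n_termini_common	457
n_termini_exclusive_rrd	182
n_termini_exclusive_control	216
c_termini_common	149
c_termini_exclusive_rrd	46
c_termini_exclusive_control	130
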