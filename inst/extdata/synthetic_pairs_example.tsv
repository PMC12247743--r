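cdr3	epitope	antigen_group
CASSLAEYGQF	GSPEIGTFL	synthA
CASSYVAEYVF	GSPEIGTFL	synthA
CASSPMKDTQF	WPIWLNQQA	synthB
CASSQMKDAYF	WPIWLNQQA	synthB
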