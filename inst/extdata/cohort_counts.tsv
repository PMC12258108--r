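dataset	data_type	n_patients	n_positive
GSE49710	bulk	498	269
E-MTAB-1781	bulk	709	398
GSE192906	single_cell	10	2
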