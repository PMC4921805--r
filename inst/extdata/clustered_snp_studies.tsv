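study	region	clustered	conventional
ltr_panel	LTRs	25	109
msy_ngs_all	whole MSY	350	42035
msy_ngs_filtered	whole MSY	256	33072
msy_sanger_unique	unique MSY (1.5 Mb)	28	3362
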