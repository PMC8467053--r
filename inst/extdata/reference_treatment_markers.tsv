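# reference treated-vs-control tumor comparison (reported study values):
# log2FC is control vs treated (negative = elevated under treatment),
# p from the Wilcoxon rank-sum test on section mean intensities, AUC from
# pixel-level ROC; group = arm with elevated intensity
mz	log2fc	p	auc	group
768.6	-0.34	0.01	0.71	treated
784.6	-0.23	0.08	0.70	treated
786.6	-0.19	0.08	0.75	treated
790.6	-0.30	0.03	0.70	treated
812.6	-0.42	0.03	0.70	treated
604.7	1.11	0.06	0.87	control
779.3	0.53	0.01	0.65	control
801.2	0.50	0.01	0.64	control
867.2	0.58	0.02	0.63	control
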