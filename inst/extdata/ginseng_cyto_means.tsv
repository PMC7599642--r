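# Per-line cytogenetic means for the three cultivated cell lines:
# mean macro (>=2 um) and micro (<2 um) nucleoli per interphase nucleus
# and mean chromosomes per metaphase cell (micro nucleoli were not
# observed in the young line 9s).
line	macro_mean	micro_mean	chr_mean
9s	1.2	0	42.3
1s	5.6	4.3	63.8
1o	6.3	5.5	65.5
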