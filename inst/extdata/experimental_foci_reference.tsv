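# Externally measured reference constants: mean gamma-H2AX foci per
# endothelial-cell nucleus (G0/G1), 30 min post-irradiation, >= 3
# replicate experiments; errors are standard errors.  Comparison
# fixture only -- never recomputed by this package.
beam	dose_Gy	foci_mean	foci_se
40kVp	0.25	5.35	1.13
40kVp	0.5	9.88	0.87
40kVp	1	18.59	0.43
40kVp	2	30.30	2.21
220kVp	0.25	7.35	2.17
220kVp	0.5	10.24	1.73
220kVp	1	18.64	2.33
220kVp	2	30.59	2.96
4MV	0.25	4.35	0.21
4MV	0.5	8.54	1.42
4MV	1	16.46	1.63
4MV	2	26.42	0.87
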