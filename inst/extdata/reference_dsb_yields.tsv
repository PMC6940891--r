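# Reference DSB yields from a full event-by-event track-structure
# computation chain, packaged as comparison constants for the same
# three beams and chemistry end-times.  Errors are the standard
# deviation of the mean over 10 batches.
beam	end_time_ns	dsb_per_gy_per_gbp	sd	simple_pct	simple_sd	complex_pct	complex_sd
40kVp	2.5	3.5	0.3	86.0	3.3	14.0	3.3
40kVp	10	4.7	0.3	86.3	1.8	13.7	1.8
220kVp	2.5	3.5	0.3	86.4	2.1	13.6	2.1
220kVp	10	4.7	0.2	86.2	2.1	13.8	2.1
4MV	2.5	2.8	0.3	87.7	2.9	12.3	2.9
4MV	10	3.6	0.3	86.5	2.3	13.5	2.3
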