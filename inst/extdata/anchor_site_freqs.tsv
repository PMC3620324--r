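# Per-group nucleotide frequencies (%) at COI alignment columns 640-643,
# the 3' anchor binding site of the predator-specific blocking primers.
# Groups: decapod (947 seqs), fish (758 seqs), gastropod (271 seqs).
# The gastropod %G at 641 is corrected to 0 (printed-table duplication typo).
group	position	%A	%C	%T	%G
decapod	640	12.7	24.9	59.5	2.9
decapod	641	0	65.5	34.5	0
decapod	642	0	0.1	99.9	0
decapod	643	43.7	17.6	28	10.8
fish	640	0.2	40.3	59.5	0
fish	641	0	92.9	7.1	0
fish	642	0	0.1	99.9	0
fish	643	17.1	26	44.2	12.7
gastropod	640	3.3	15.1	0.7	80.8
gastropod	641	0	33.6	66.4	0
gastropod	642	0	0	100	0
gastropod	643	58.7	6.3	5.9	29.2
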