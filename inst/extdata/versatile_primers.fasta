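>LCO1490 forward
GGTCAACAAATCATAAAGATATTGG
>HCO2198 reverse
TAAACTTCAGGGTGACCAAAAAATCA
>dgLCO1490 forward
GGTCAACAAATCATAAAGAYATYGG
>dgHCO2198 reverse
TAAACTTCAGGGTGACCAAARAAYCA
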