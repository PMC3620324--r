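>N_armatus_blocker 5'-3', 3' SpacerC3
CAAAGAATCAAAACAGGTGTTGATAAAGA
>P_arcatus_blocker 5'-3', 3' SpacerC3
CAAAGAATCAGAACAGATGTTGGTAAAGA
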