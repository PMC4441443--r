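HEADER    SYNTHETIC EXAMPLE PROTEIN               01-JAN-14   2SYN
EXPDTA    SOLUTION NMR
REMARK 210  EXPERIMENT TYPE                : NMR
REMARK 210  TEMPERATURE           (K) : 298
REMARK 210  PH                            : 7.0
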