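==== Secondary Structure Definition by the program DSSP, synthetic example file ====
REFERENCE  synthetic fixture for parser tests .
  4  2  2  0  0 TOTAL NUMBER OF RESIDUES, NUMBER OF CHAINS
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA
    1    1 A M                     100      0, 0.0
    2    2 A L                      14      0, 0.0
    3    3 A a                      28      0, 0.0
    4    4 A X                      30      0, 0.0
    5        !                              
    6    1 B K                     180      0, 0.0
    7    2 B S                     110      0, 0.0
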