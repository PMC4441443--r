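# synthetic select-25 list
2SYN_A
2SYN_B
1AAA_A
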