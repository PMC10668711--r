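phase,lying,sitting_standing,jute_rooting
before,0.717,0.033,0.250
during,0.935,0.062,0.003
after,1.000,0.000,0.000
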