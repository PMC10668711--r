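policy,FP,FN,CP,CN
wrong_as_FN,10751,1823,1509,1582
wrong_as_CP,10751,76,3256,1582
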