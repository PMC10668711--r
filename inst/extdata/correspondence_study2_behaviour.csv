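zone,label
head,playing_with_sack
head,eating
trough,eating
rump,standing
fence,standing
fence,moving_leg_lying
outside_pen,none
cloud,none
none,lying_down
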