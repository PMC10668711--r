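zone,label
head,front_of_pen
rump,metal_fence
fence,metal_fence
head,trough
trough,trough
outside_pen,neighbour_sow
cloud,neighbour_sow
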