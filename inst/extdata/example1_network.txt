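# 3-node demonstration network: one singleton attractor [0,1,0] and one
# period-2 cyclic attractor [1,1,0] <-> [0,0,1].
v1, !v2
v2, !v1 | v3
v3, v1
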