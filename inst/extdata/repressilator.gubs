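# Three-gene mutual-inhibition ring (design goal).
# g1 and g2 are variable genes to be resolved by the compiler;
# TetR_lite is a named part that must appear in the assembly.
g1 o-> !g2
g2 o-> !TetR_lite
TetR_lite o-> !g1
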