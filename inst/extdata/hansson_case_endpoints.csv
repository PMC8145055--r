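label,x1,y1,z1,x2,y2,z2
proximal_top,21.4,-26.7,58,21.1,-19.5,57.5
proximal_bottom,-16.2,17.6,2.96,-18.3,19.5,-2.02
distal_top,30.1,-36.7,47.7,30.1,-30.3,46.5
distal_bottom,-14.3,12.1,-14,-15.9,16.3,-18.1
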