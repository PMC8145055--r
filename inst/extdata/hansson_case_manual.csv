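label,manual_mm
proximal_top,3.30
proximal_bottom,4.56
distal_top,4.92
distal_bottom,4.48
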