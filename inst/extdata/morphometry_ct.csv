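"id","parent","length_mm","radius_mm"
"trachea",,6,0.75
"main_L","trachea",4,0.55
"main_R","trachea",3.8,0.6
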