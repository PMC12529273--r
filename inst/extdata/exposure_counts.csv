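exposure,class,case,control
susceptibility,low,25,21
susceptibility,moderate,92,123
susceptibility,high,47,65
distance,low,19,11
distance,moderate,82,100
distance,high,63,98
density,low,43,41
density,moderate,95,137
density,high,26,31
roads,low,31,37
roads,moderate,70,91
roads,high,63,81
landuse,low,6,17
landuse,moderate,150,190
landuse,high,8,2
fog,low,12,17
fog,high,152,192
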