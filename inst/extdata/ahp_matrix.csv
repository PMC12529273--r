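criterion,distance,density,landuse,roads,fog
distance,1,1,5,5,7
density,1,1,5,5,7
landuse,1/5,1/5,1,3,5
roads,1/5,1/5,1/5,1,5
fog,1/7,1/7,1/5,1/5,1
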