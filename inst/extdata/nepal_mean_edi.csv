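element,mean_edi_ug_per_kg_day
Cd,0.108
As,0.250
Pb,0.100
Cu,6.35
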