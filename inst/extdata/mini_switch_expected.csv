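"flip_fraction","alignment_pre","alignment_post","median_peak_dprime"
"1","0.957540865924487","-0.386882403743104","1.21821407896638"
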