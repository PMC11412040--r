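category,stable,relapse_outpt,relapse_hosp
compliant,0.88,0.74,0.53
partial,0.75,0.63,0.53
non,0.75,0.63,0.42
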