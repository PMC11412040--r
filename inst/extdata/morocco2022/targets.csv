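strategy,stable,hosp,outpt
olanzapine_sot,79,11,10
risperidone_sot,62,19,19
aripiprazole_sot,50,26,24
olanzapine_odt,79,11,10
risperidone_odt,62,19,19
aripiprazole_odt,50,26,24
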