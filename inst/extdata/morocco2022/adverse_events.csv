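strategy,eps,weight_gain,diabetes
olanzapine_sot,16,30,3
risperidone_sot,25,14,3
aripiprazole_sot,21,7,2
olanzapine_odt,16,30,3
risperidone_odt,25,14,3
aripiprazole_odt,21,7,2
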