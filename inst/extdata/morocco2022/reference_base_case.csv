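strategy,type,cost,qaly
olanzapine_odt,arm,3034,0.7916
olanzapine_sot,arm,3106,0.7733
risperidone_odt,arm,3710,0.7850
risperidone_sot,arm,3811,0.7666
aripiprazole_odt,arm,3675,0.7822
aripiprazole_sot,arm,3728,0.7633
olanzapine,group,6140,1.5650
risperidone,group,7521,1.5517
aripiprazole,group,7403,1.5456
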