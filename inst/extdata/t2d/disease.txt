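name T2D
state Organ,circulation,metabolite,glucose = high
state Cell,hepatocyte,process,insulin_resistance = high
state Cell,adipocyte,process,insulin_resistance = high
state Cell,muscle,process,insulin_resistance = high
disease_rule t2d_hepatocyte_ir
disease_rule t2d_adipocyte_ir
disease_rule t2d_muscle_ir
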