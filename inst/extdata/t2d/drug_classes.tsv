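name	class	target
metformin	hepatic sensitizer	Cell,hepatocyte,gene,PRKAB1
pioglitazone	sensitizer	Cell,adipocyte,gene,PPARG
rosiglitazone	sensitizer	Cell,adipocyte,gene,PPARG
troglitazone	sensitizer	Cell,adipocyte,gene,PPARG
saxagliptin	secretagogue	Cell,beta-cell,process,insulin_secretion
sitagliptin	secretagogue	Cell,beta-cell,process,insulin_secretion
vildagliptin	secretagogue	Cell,beta-cell,process,insulin_secretion
miglitol	secretagogue	Cell,beta-cell,process,insulin_secretion
voglibose	secretagogue	Cell,beta-cell,process,insulin_secretion
acarbose	secretagogue	Cell,beta-cell,process,insulin_secretion
exenatide	secretagogue	Cell,beta-cell,process,insulin_secretion
liraglutide	secretagogue	Cell,beta-cell,process,insulin_secretion
mitiglinide	secretagogue	Cell,beta-cell,process,insulin_secretion
nateglinide	secretagogue	Cell,beta-cell,process,insulin_secretion
repaglinide	secretagogue	Cell,beta-cell,process,insulin_secretion
chlorpropamide	secretagogue	Cell,beta-cell,process,insulin_secretion
glipizide	secretagogue	Cell,beta-cell,process,insulin_secretion
gliquidone	secretagogue	Cell,beta-cell,process,insulin_secretion
tolbutamide	secretagogue	Cell,beta-cell,process,insulin_secretion
glimepiride	secretagogue	Cell,beta-cell,process,insulin_secretion
glyburide	secretagogue	Cell,beta-cell,process,insulin_secretion
pramlintide	secretagogue	Cell,beta-cell,process,insulin_secretion
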