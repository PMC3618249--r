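metformin
pioglitazone
rosiglitazone
troglitazone
saxagliptin
sitagliptin
vildagliptin
miglitol
voglibose
acarbose
exenatide
liraglutide
mitiglinide
nateglinide
repaglinide
chlorpropamide
glipizide
gliquidone
tolbutamide
glimepiride
glyburide
pramlintide
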