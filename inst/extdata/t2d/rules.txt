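met_prkab1: Drug,metformin,presence,status,present -> Cell,hepatocyte,gene,PRKAB1,up @src=metformin activates hepatic AMPK (PRKAB1)
prkab1_agrp: Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,AGRP,up @src=AMPK induces AGRP
prkab1_glut4: Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,GLUT4,up @src=AMPK promotes GLUT4 glucose transport
prkab1_pepck: Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,PEPCK,down @src=AMPK represses gluconeogenic PEPCK
prkab1_g6pase: Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,gene,Glucose-6-phosphatase,down @src=AMPK represses Glucose-6-phosphatase
prkab1_ir: Cell,hepatocyte,gene,PRKAB1,up -> Cell,hepatocyte,process,insulin_resistance,down @src=hepatic sensitization
gng_glucose: Cell,hepatocyte,gene,PEPCK,down & Cell,hepatocyte,gene,Glucose-6-phosphatase,down & Organ,circulation,metabolite,glucose,up -> Organ,circulation,metabolite,glucose,down @persistent @src=reduced gluconeogenesis lowers blood glucose
glut4_glucose: Cell,hepatocyte,gene,GLUT4,up & Organ,circulation,metabolite,glucose,up -> Organ,circulation,metabolite,glucose,down @persistent @src=GLUT4-mediated glucose disposal
pparg_adipo_ir: Cell,adipocyte,gene,PPARG,up -> Cell,adipocyte,process,insulin_resistance,down @src=PPARG relieves adipocyte insulin resistance
pparg_muscle_ir: Cell,adipocyte,gene,PPARG,up -> Cell,muscle,process,insulin_resistance,down @src=adipokine signalling sensitizes muscle
pparg_uptake: Cell,adipocyte,gene,PPARG,up -> Cell,muscle,process,glucose_uptake,up @src=sensitized muscle takes up more glucose
uptake_glucose: Cell,muscle,process,glucose_uptake,up & Organ,circulation,metabolite,glucose,up -> Organ,circulation,metabolite,glucose,down @persistent @src=muscle glucose uptake lowers blood glucose
secretion_ins: Cell,beta-cell,process,insulin_secretion,up -> Cell,beta-cell,gene,INS,up @src=secretory demand induces insulin gene expression
secretion_insulin: Cell,beta-cell,process,insulin_secretion,up & Organ,circulation,metabolite,glucose,up -> Organ,circulation,hormone,insulin,up @persistent @src=glucose-stimulated insulin secretion
insulin_glucose: Organ,circulation,hormone,insulin,up & Organ,circulation,metabolite,glucose,up -> Organ,circulation,metabolite,glucose,down @persistent @src=insulin drives glucose disposal
pioglitazone_target: Drug,pioglitazone,presence,status,present -> Cell,adipocyte,gene,PPARG,up @src=sensitizer drug target
rosiglitazone_target: Drug,rosiglitazone,presence,status,present -> Cell,adipocyte,gene,PPARG,up @src=sensitizer drug target
troglitazone_target: Drug,troglitazone,presence,status,present -> Cell,adipocyte,gene,PPARG,up @src=sensitizer drug target
saxagliptin_target: Drug,saxagliptin,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
sitagliptin_target: Drug,sitagliptin,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
vildagliptin_target: Drug,vildagliptin,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
miglitol_target: Drug,miglitol,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
voglibose_target: Drug,voglibose,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
acarbose_target: Drug,acarbose,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
exenatide_target: Drug,exenatide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
liraglutide_target: Drug,liraglutide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
mitiglinide_target: Drug,mitiglinide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
nateglinide_target: Drug,nateglinide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
repaglinide_target: Drug,repaglinide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
chlorpropamide_target: Drug,chlorpropamide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
glipizide_target: Drug,glipizide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
gliquidone_target: Drug,gliquidone,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
tolbutamide_target: Drug,tolbutamide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
glimepiride_target: Drug,glimepiride,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
glyburide_target: Drug,glyburide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
pramlintide_target: Drug,pramlintide,presence,status,present -> Cell,beta-cell,process,insulin_secretion,up @src=secretagogue drug target
t2d_hepatocyte_ir: Cell,hepatocyte,process,insulin_resistance,up & Organ,circulation,metabolite,glucose,down -> Organ,circulation,metabolite,glucose,up @disease @persistent @src=insulin resistance sustains hyperglycaemia
t2d_adipocyte_ir: Cell,adipocyte,process,insulin_resistance,up & Organ,circulation,metabolite,glucose,down -> Organ,circulation,metabolite,glucose,up @disease @persistent @src=insulin resistance sustains hyperglycaemia
t2d_muscle_ir: Cell,muscle,process,insulin_resistance,up & Organ,circulation,metabolite,glucose,down -> Organ,circulation,metabolite,glucose,up @disease @persistent @src=insulin resistance sustains hyperglycaemia
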