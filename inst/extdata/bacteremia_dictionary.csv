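name,label,scale,units,role,lower,upper,component_of,ratio_of
ID,Patient identification,nominal,,identifier,,,,
BloodCulture,Blood culture result for bacteremia,binary,"no, yes",outcome,,,,
AGE,Patient age,continuous,years,structural,16,101,,
SEX,Patient sex,nominal,"1 = male, 2 = female",structural,,,,
WBC,White blood count,continuous,G/L,key,0,200,,
BUN,Blood urea nitrogen,continuous,mg/dl,key,0,300,,
CREA,Creatinine,continuous,mg/dl,key,0,40,,
NEU,Neutrophiles,continuous,G/L,key,0,200,WBC,
PLT,Blood platelets,continuous,G/L,key,0,2000,,
ALAT,Alanin transaminase,continuous,U/L,medium,,,,
ASAT,Aspartate transaminase,continuous,U/L,medium,,,,
CRP,C-reactive protein,continuous,mg/dl,medium,,,,
GGT,Gamma-glutamyl transpeptidase,continuous,G/L,medium,,,,
FIB,Fibrinogen,continuous,mg/dl,medium,,,,
POTASS,Potassium,continuous,mmol/L,medium,,,,
ALB,Albumin,continuous,G/L,minor,,,,
AMY,Amylase,continuous,U/L,minor,,,,
AP,Alkaline phosphatase,continuous,U/L,minor,,,,
APTT,Activated partial thromboplastin time,continuous,sec,minor,,,,
BASO,Basophiles,continuous,G/L,minor,,,WBC,
BASOR,Basophile ratio,continuous,%,minor,,,,BASO
CA,Calcium,continuous,mmol/L,minor,,,,
CHE,Cholinesterase,continuous,kU/L,minor,,,,
CHOL,Cholesterol,continuous,mg/dl,minor,,,,
CK,Creatinine kinases,continuous,U/L,minor,,,,
EOS,Eosinophils,continuous,G/L,minor,,,WBC,
EOSR,Eosinophil ratio,continuous,%,minor,,,,EOS
GBIL,Bilirubin,continuous,mg/dl,minor,,,,
GLU,Glucoses,continuous,mg/dl,minor,,,,
HCT,Haematocrit,continuous,%,minor,,,,
HGB,Haemoglobin,continuous,G/L,minor,,,,
HS,Uric acid,continuous,mg/dl,minor,,,,
LDH,Lactate dehydrogenase,continuous,U/L,minor,,,,
LIP,Lipases,continuous,U/L,minor,,,,
LYM,Lymphocytes,continuous,G/L,minor,,,WBC,
LYMR,Lymphocyte ratio,continuous,%,minor,,,,LYM
MCH,Mean corpuscular hemoglobin,continuous,fl,minor,,,,
MCHC,Mean corpuscular hemoglobin concentration,continuous,g/dl,minor,,,,
MCV,Mean corpuscular volume,continuous,pg,minor,,,,
MG,Magnesium,continuous,mmol/L,minor,,,,
MONO,Monocytes,continuous,G/L,minor,,,WBC,
MONOR,Monocyte ratio,continuous,%,minor,,,,MONO
MPV,Mean platelet volume,continuous,fl,minor,,,,
NEUR,Neutrophile ratio,continuous,%,minor,,,,NEU
NT,Normotest,continuous,%,minor,,,,
PAMY,Pancreas amylase,continuous,U/L,minor,,,,
PDW,Platelet distribution width,continuous,%,minor,,,,
PHOS,Phosphate,continuous,mmol/L,minor,,,,
RBC,Red blood count,continuous,T/L,minor,,,,
RDW,Red blood cell distribution width,continuous,%,minor,,,,
SODIUM,Sodium,continuous,mmol/L,minor,,,,
TP,Total protein,continuous,G/L,minor,,,,
TRIG,Triclyceride,continuous,mg/dl,minor,,,,
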