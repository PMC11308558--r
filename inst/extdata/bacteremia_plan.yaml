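# Screening plan for the bacteremia diagnostic study: three candidate
# models (key predictors; key + medium importance; all predictors), the
# structural variables age and sex as the set every candidate includes.
model_sets:
  structural: [AGE, SEX]
  key: [AGE, SEX, WBC, BUN, CREA, NEU, PLT]
  key_medium: [AGE, SEX, WBC, BUN, CREA, NEU, PLT, ALAT, ASAT, CRP, GGT, FIB, POTASS]
  all: [AGE, SEX, WBC, BUN, CREA, NEU, PLT, ALAT, ASAT, CRP, GGT, FIB, POTASS,
        ALB, AMY, AP, APTT, BASO, BASOR, CA, CHE, CHOL, CK, EOS, EOSR, GBIL,
        GLU, HCT, HGB, HS, LDH, LIP, LYM, LYMR, MCH, MCHC, MCV, MG, MONO,
        MONOR, MPV, NEUR, NT, PAMY, PDW, PHOS, RBC, RDW, SODIUM, TP, TRIG]
interactions: []
quantiles: [0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95]
pseudolog:
  sigma: 1
  base: 10
structural_strata: decades
seed: 1
min_pairs: 30
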