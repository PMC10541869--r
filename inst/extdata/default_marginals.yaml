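# Default marginal distributions for the synthetic cohort generator.
# These are plausible synthetic values for an Australian-style waitlist and
# donor pool, chosen so the simulator runs with zero downloads; they are NOT
# registry estimates. Every categorical block must sum to 1.

dates:
  start: "2006-06-30"
  end: "2017-11-13"

age:
  bands:
    - {min: 1,  max: 17, p: 0.05}
    - {min: 18, max: 44, p: 0.30}
    - {min: 45, max: 64, p: 0.45}
    - {min: 65, max: 80, p: 0.20}

donor_age:
  bands:
    - {min: 1,  max: 17, p: 0.04}
    - {min: 18, max: 44, p: 0.31}
    - {min: 45, max: 64, p: 0.45}
    - {min: 65, max: 85, p: 0.20}

sex: {F: 0.38, M: 0.62}

blood_group: {O: 0.49, A: 0.38, B: 0.10, AB: 0.03}

state:
  NSW: 0.315
  VIC: 0.255
  QLD: 0.200
  WA:  0.105
  SA:  0.070
  TAS: 0.021
  ACT: 0.018
  NT:  0.016

# PRA in percent; a point mass at 0 for unsensitized candidates, then
# uniform within bands.
pra:
  bands:
    - {min: 0,  max: 0,   p: 0.55}
    - {min: 1,  max: 20,  p: 0.20}
    - {min: 21, max: 50,  p: 0.12}
    - {min: 51, max: 80,  p: 0.08}
    - {min: 81, max: 100, p: 0.05}

comorbidity:
  lung_disease: 0.08
  smoking: 0.22
  diabetes: 0.35
  cardiovascular_disease: 0.25
  cancer: 0.05

prior_kidney_transplant: 0.12

dialysis:
  p_on_dialysis: 0.92   # fraction listed while already on dialysis
  mean_years: 2.0       # mean dialysis vintage at listing (exponential)

kdri: {meanlog: 0.0, sdlog: 0.3}   # log-normal; median 1.0 = reference donor

# Broad-antigen allele pools per locus (two alleles drawn per person).
hla:
  A:
    A1: 0.16
    A2: 0.28
    A3: 0.13
    A11: 0.08
    A24: 0.14
    A26: 0.05
    A68: 0.06
    A31: 0.05
    A32: 0.05
  B:
    B7: 0.12
    B8: 0.11
    B27: 0.05
    B35: 0.10
    B44: 0.14
    B51: 0.07
    B57: 0.05
    B60: 0.07
    B62: 0.08
    B18: 0.06
    B13: 0.05
    B14: 0.10
  DR:
    DR1: 0.10
    DR3: 0.12
    DR4: 0.15
    DR7: 0.13
    DR11: 0.12
    DR13: 0.11
    DR15: 0.15
    DR8: 0.12
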