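# Canonical model configuration: ractopamine in the 30 kg goat.
# Organ weights and regional flows are literature/study fractions;
# drug-specific values are the fitted final estimates.  Cardiac output,
# brain/spleen flows, blood volume and its arterial split, and the
# tissue vascular fractions are documented package defaults (the study
# did not print them); see the methods vignette.
physiology:
  body_mass: 30.0                 # kg
  cardiac_output: 5.97            # L/h per kg BW (lung flow basis)
  organ_mass_fraction:            # fraction of body weight
    liver: 0.0129
    kidney: 0.0031
    muscle: 0.3527
    lung: 0.0078
    fat: 0.0274
    brain: 0.0032
    spleen: 0.0028
    heart: 0.0035
    rest: 0.5866
  organ_flow_fraction:            # fraction of cardiac output
    liver: 0.4832                 # total hepatic inflow (incl. splenic)
    kidney: 0.1705
    muscle: 0.1400
    fat: 0.0850
    heart: 0.0498
    rest: 0.0715
  brain_flow_fraction: 0.02       # carved out of 'rest'
  spleen_flow_fraction: 0.02      # part of the hepatic total
  blood_volume_fraction: 0.07     # of BW; carved out of 'rest' mass
  arterial_fraction: 0.3333333333333333
  tissue_blood_fraction:          # vascular space of membrane tissues
    muscle: 0.04
    fat: 0.02
    brain: 0.04
    rest: 0.04
  hematocrit: 0.30
drug:
  partition:                      # tissue:plasma
    liver: 2.5584
    kidney: 1.7734
    spleen: 1.0047
    heart: 1.3839
    lung: 1.5333
    muscle: 1.0686
    fat: 0.7526
    brain: 0.6896
    rest: 9.0888
  permeability_fraction:          # fraction of tissue blood flow
    muscle: 0.0271
    fat: 0.0054
    brain: 0.0068
    rest: 0.0021
  cl_hepatic: 0.0624              # L/h/kg BW
  cl_renal: 0.0001                # L/h/kg BW
  k_stomach: 0.0910               # 1/h, gastric emptying
  k_absorption: 0.9861            # 1/h
  k_gut: 0.9016                   # 1/h, fecal loss
  free_fraction: 1.0
options:
  absorption_form: standard
  permeability_mode: flow
  blood_plasma_ratio: 1.0
  interp: linear
  rtol: 1.0e-8
  atol: 1.0e-10
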