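quintile,energy_kcal,protein_g,vita_ug_rae,vitc_mg,fe_mg,zn_mg
I,2050.97,67.61,755.88,84.51,23.44,15.66
II,2001.59,69.74,875.54,99.56,22.84,15.54
III,2000.89,72.02,928.20,114.63,22.81,15.69
IV,2049.98,75.93,1003.78,128.04,22.83,15.94
V,2202.20,84.14,1105.25,154.86,25.03,17.30
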