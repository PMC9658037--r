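trait,F1,F2,F3,F4,F5,communality,specificity
yam_mosaic_virus,0.01,-0.21,0.34,0.75,-0.06,0.72,0.28
pasting_temperature,0.52,-0.37,0.12,0.36,-0.40,0.72,0.28
pasting_time,-0.01,-0.89,-0.06,0.00,-0.13,0.81,0.19
peel_loss,-0.04,0.19,0.93,-0.02,0.04,0.91,0.09
leaf_chlorophyll,0.10,-0.06,0.01,-0.59,0.30,0.46,0.54
stem_number,-0.94,0.16,-0.09,0.00,0.00,0.92,0.08
stem_diameter,0.76,0.18,-0.09,-0.26,-0.06,0.70,0.30
tuber_number,-0.89,-0.03,-0.12,0.01,0.12,0.82,0.18
tuber_yield,-0.03,0.10,-0.01,-0.87,-0.12,0.78,0.22
dry_matter,-0.35,0.25,-0.25,-0.14,0.69,0.74,0.26
peak_viscosity,-0.40,0.49,-0.30,-0.15,0.51,0.77,0.23
holding_strength,-0.07,-0.90,0.04,0.13,0.04,0.83,0.17
breakdown_value,-0.24,0.87,-0.15,-0.09,0.14,0.86,0.14
final_paste_viscosity,-0.27,-0.77,-0.11,0.04,0.37,0.81,0.19
starch_yield,-0.19,0.23,-0.71,-0.03,0.55,0.89,0.11
flour_yield,-0.01,0.13,-0.85,-0.30,0.16,0.86,0.14
protein_content,-0.16,0.20,0.00,0.03,-0.75,0.64,0.36
ash_content,-0.60,-0.08,0.28,-0.31,-0.35,0.66,0.34
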