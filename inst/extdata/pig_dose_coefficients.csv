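# Reference cohort: per-subject absorbed-dose coefficients (mGy/MBq) for a
# 70-kg adult male phantom, five pigs, Lu-177 somatostatin-antagonist study.
target,pig1,pig2,pig3,pig4,pig5
adrenals,6.82e-2,7.69e-2,6.12e-2,7.39e-2,6.69e-2
brain,5.80e-2,6.74e-2,5.24e-2,5.90e-2,5.88e-2
breasts,5.59e-2,6.74e-2,5.14e-2,5.87e-2,5.66e-2
gallbladder_wall,6.61e-2,7.55e-2,5.91e-2,7.08e-2,6.61e-2
lli_wall,6.06e-2,7.10e-2,5.49e-2,6.55e-2,6.10e-2
small_intestine,6.20e-2,7.25e-2,5.65e-2,6.65e-2,6.21e-2
stomach_wall,6.13e-2,7.23e-2,5.61e-2,6.55e-2,6.13e-2
uli_wall,6.19e-2,7.24e-2,5.64e-2,6.62e-2,6.20e-2
heart_wall,1.10e-1,4.44e-1,9.35e-2,1.38e-1,1.23e-1
kidneys,2.71,2.17,2.55,4.46,1.76
liver,2.37e-1,1.68e-1,1.27e-1,2.17e-1,2.64e-1
lungs,5.94e-2,7.10e-2,5.39e-2,6.19e-2,6.01e-2
muscle,5.89e-2,6.92e-2,5.36e-2,6.20e-2,5.93e-2
ovaries,6.10e-2,7.16e-2,5.54e-2,6.60e-2,6.14e-2
pancreas,6.57e-2,7.60e-2,5.95e-2,7.09e-2,6.51e-2
red_marrow,2.17e-1,7.72e-2,1.05e-1,7.00e-2,2.25e-1
osteogenic_cells,1.34,3.75e-1,5.73e-1,2.76e-1,1.38
skin,5.58e-2,6.62e-2,5.11e-2,5.85e-2,5.64e-2
spleen,6.48e-2,7.48e-2,5.95e-2,7.13e-2,6.34e-2
testes,5.73e-2,6.81e-2,5.24e-2,6.16e-2,5.79e-2
thymus,5.84e-2,7.21e-2,5.35e-2,6.12e-2,5.92e-2
thyroid,5.85e-2,6.91e-2,5.34e-2,6.04e-2,5.92e-2
urinary_bladder_wall,2.44e-1,1.58e-1,5.78e-2,1.15,1.64e-1
uterus,6.13e-2,7.19e-2,5.53e-2,6.96e-2,6.14e-2
total_body,1.02e-1,8.76e-2,7.64e-2,8.87e-2,9.98e-2
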