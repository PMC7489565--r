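# Printed positive-ion-mode assignments for tetromadurin (C42H64O12) from the
# published spectrum legend. m/z values are instrument observations
# (unit-resolution ion trap); intensities are synthetic, chosen only so the
# sodium adduct is the base peak as the text describes.
# The printed [M+H-H2O]+ value (739.84) is inconsistent with the other ions
# (computed average-mass value ~743.95; the analogous ion of the des-hydroxy
# metabolite prints 16 Da below at 727.70) and is transcribed here as printed.
mz,intensity
783.81,100
778.82,45
761.84,30
739.84,12
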