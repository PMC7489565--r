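# Printed positive-ion-mode assignments for the knockout shunt metabolite
# T-17 (C42H64O11) from the published spectrum legend. m/z values are
# instrument observations; intensities are synthetic, chosen only so the
# water-loss ion is the base peak as the text describes.
mz,intensity
767.69,55
762.58,40
745.63,35
727.70,100
709.79,18
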