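# Post-PKS tailoring reaction table for the tetronate pathway.
# Deltas are signed element counts applied to the free-acid chain formula.
# The tetronate-formation delta (IX) is the exact element difference between
# the chain free acid plus a glyceryl unit and the post-condensation
# intermediate: adding glyceric acid (C3H6O4) with loss of two waters gives
# a net +C3H2O2. The hydration + tetrahydropyran rearrangement is one
# formula-neutral composite step (XVII): the pathway is agnostic about
# whether the hemiacetal or the ketone form is the cyclase substrate.
# Precursor-supply steps (glyceryl-ACP / methoxymalonyl-ACP biosynthesis) are
# capability gates, not reactions on the chain.
steps:
- id: IX
  name: tetronate formation and chain release
  genes: [mad16, mad7, mad8]
  capability: has_glycerate_operon
  delta: {C: 3, H: 2, O: 2}
  prerequisites: []
  site: C1-C2 + glyceryl unit (C40-C42)
- id: XII
  name: acetylation of the C41 hydroxyl
  genes: [mad17]
  capability: has_glycerate_operon
  delta: {C: 2, H: 2, O: 1}
  prerequisites: [IX]
  site: C41
- id: XIII
  name: acetate elimination forming the C40-C41 exocyclic double bond
  genes: [mad18]
  capability: has_glycerate_operon
  delta: {C: -2, H: -4, O: -2}
  prerequisites: [XII]
  site: C40-C41
- id: X
  name: epoxidation of the C24-C25 and C28-C29 E double bonds
  genes: [madC]
  capability: has_epoxidase_hydrolase_pair
  delta: {O: 2}
  prerequisites: [IX]
  site: C24-C25, C28-C29
- id: XI
  name: epoxide-opening cascade forming the two tetrahydrofuran rings
  genes: [madB]
  capability: has_epoxidase_hydrolase_pair
  delta: {}
  prerequisites: [X]
  site: C21-C24, C25-C28
- id: XIV
  name: hydroxylation of C36
  genes: [mad29]
  capability: two_p450s
  delta: {O: 1}
  prerequisites: [IX]
  site: C36
- id: XV
  name: "[4+2] cycloaddition forming the oxadecalin"
  genes: [mad10]
  capability: pyrE3_like_cyclase
  delta: {}
  prerequisites: [XI]
  site: oxadecalin (cyclohexane precursor)
- id: XVII
  name: hydration and tetrahydropyran formation (composite)
  genes: [mad31]
  capability: vstJ_like_cyclase
  delta: {}
  prerequisites: [XV]
  site: tetrahydropyran; dismantles the oxadecalin
- id: XVIII
  name: hydroxylation of C38
  genes: [mad30]
  capability: two_p450s
  delta: {O: 1}
  prerequisites: [XV]
  site: C38
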