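---
title: "From a modular PKS gene cluster to a predicted product: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a modular PKS gene cluster to a predicted product: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksmith)
```

## The inference problem

Type I modular polyketide synthases (PKSs) are assembly lines: each module
performs one round of chain extension, and the catalytic domains it carries
(ketosynthase KS, acyltransferase AT, dehydratase DH, enoylreductase ER,
ketoreductase KR, acyl-carrier protein ACP) determine which extender unit is
incorporated and how far the new beta-keto group is reduced. Collinearity —
module order matching the order of chemical features along the chain — makes
the final product largely predictable from sequence. `pksmith` implements
that prediction as a tested pipeline for tetronate-type polyethers, with the
tetromadurin (*mad*) cluster of *Actinomadura verrucosospora* as the packaged
worked instance: seven PKS multienzymes carrying a loading module plus 14
extension modules, a tetronate-forming glycerate operon, a methoxymalonate
subcluster, epoxidase/epoxide-hydrolase tetrahydrofuran chemistry, two [4+2]
cyclases and two cytochrome P450s.

## Reference-anchored motif calls

The published domain assignments rest on reading specific alignment columns:
the KS C-H-H catalytic triad (a glutamine in place of the cysteine marks the
decarboxylating loading KS^Q); the 4-residue AT selectivity motif
((H/T/V/Y)AFH for malonyl-CoA, (Y/V/W)ASH for (2S)-methylmalonyl-CoA, and the
hybrid HASH of relaxed-selectivity loading ATs); the DH YGP tyrosine and the
catalytic aspartate of the HPALLDAAL context; the KR (L/V/I)DD motif,
NADPH-binding window, catalytic tyrosine and the proline two residues after
it; and the single ER tyrosine that separates L- from D-configuring domains.

`pksmith` encodes each of these as an *anchor column* on a packaged synthetic
consensus scaffold (one per domain kind, built once from the published motif
descriptions; anchor coordinates are a package convention, recorded in the
output metadata, not literature alignment numbering). A domain is globally
aligned to its scaffold (Needleman–Wunsch, BLOSUM62, affine gaps via
`Biostrings::pairwiseAlignment`) and the residues under the anchors decide
the call. Matching anchored columns rather than running free regular
expressions over the whole domain avoids false positives on internal repeats
— the same reason the original analysis reads motifs off alignments.

Two thresholds matter and are exposed as arguments:

* `identity_floor` (default 0.20): below this fractional alignment identity a
  domain is rejected as "unalignable" rather than called. A wrong call is
  worse than no call.
* `nadph_gap_threshold` (default 0.50): the gap fraction in the KR NADPH
  window above which a deletion is called (the source describes only "a
  significant deletion"; the default makes half-window loss decisive).

AT pattern priority is fixed: HASH before `[HTVY]AFH` before `[YVW]ASH`, so
the documented hybrid cannot be swallowed by the acetate pattern. A hybrid
loading AT resolves to propionate only when a target decomposition demands it
(no des-methyl congener of tetromadurin is known); without a target it stays
`relaxed_hybrid` and formula-level output for the chain is refused.
Methoxymalonate-selective ATs have no motif of their own — they resemble
methylmalonyl-selective domains — so the `methoxymalonate_override` is a
cluster-level re-label applied only when the full five-gene subcluster is
present *and* the target marks the position.

Where the source material is internally inconsistent we follow the main text
and record the conflict: the diagnostic proline is attributed to B2-type KRs
(the supplementary legend says A-type), and the KR type-A rule (no LDD ⇒
L-hydroxyl) follows the cited stereochemistry literature even though the mad
cluster itself only exercises B1 and inactive KRs.

## Chain assembly and the retrobiosynthetic comparison

`assemble_from_calls()` applies the reduction ladder per module — no active
KR ⇒ ketone; KR only (or KR + inactive DH) ⇒ hydroxyl with the KR's
stereochemistry; KR + DH ⇒ enoyl; KR + DH + ER ⇒ methylene — and takes
alpha-methyl configuration from the ER in fully reducing propionate modules
or from the B1-KR rule in hydroxyl-bearing ones. The packaged target
decomposition transcribes the retrobiosynthetic reading of tetromadurin
itself: a propionate starter plus 14 extensions totalling six acetate, eight
propionate and one methoxymalonate unit.

Backbone carbons are numbered from C1 at the carboxy/tetronate-proximal end
(extension *i* of an *n*-extension chain contributes C(2(n−i)+1) and
C(2(n−i)+2); its beta carbon is C(2(n−i)+3)). The starter's three carbons are
counted as chain carbons, which reproduces the printed 31-carbon skeleton;
related tetronates are sometimes counted by a different convention (26
carbons for the tetronasin/tetronomycin skeletons) which we deliberately do
not reproduce. D/L labels are kept as labels and never converted to R/S:
the source reasons entirely in D/L, and conversion would require full
substituent-priority analysis for no analytical gain.

On the packaged fixture the module-derived and target-derived chains agree
everywhere except the position fed by module 12, whose KR lacks the catalytic
tyrosine and carries the NADPH-site deletion: annotation predicts a C7
ketone where the final structure has a D-hydroxyl. `compare_chains()` reports
exactly this discrepancy and annotates it as a candidate for a trans-acting
KR from an adjacent module, the explanation the original analysis reaches.
Because an active DH sits in the same module, the diff also notes an enoyl
product as an open alternative rather than choosing between the two.

Per-module acetate/propionate assignments are colour-coded rather than
printed in the source figures. The packaged architecture derives them from
the textual constraints (ER stereochemistry only matters in modules 4 and
11; the alpha-methyls C35 and C38 sit on modules 7 and 12; module 13 is the
methoxymalonate position; side-methyl numbering C32–C38 ascends along the
chain) and resolves the residual two-way choices (3 vs 1, 6 vs 5, 9 vs 10)
toward the published 6/8/1 precursor tally; the choices are documented in
the spec's comment block.

## Tailoring bookkeeping and knockout simulation

Post-PKS tailoring is an ordered reaction table (packaged as YAML,
user-overridable) of formula deltas with gene requirements and
prerequisites: tetronate formation and chain release (+C3H2O2 — exactly
"add glyceric acid, lose two waters"; the source gives mechanism, not
stoichiometry, so the delta is fixed by that element balance and
cross-validated by the endpoint), acetylation (+C2H2O) and elimination
(−C2H4O2) forming the exocyclic double bond, double epoxidation (+2O), the
formula-neutral tetrahydrofuran cascade, C36 hydroxylation (+O), the [4+2]
oxadecalin cycloaddition, a composite formula-neutral hydration +
tetrahydropyran step (the pathway is agnostic about whether the hemiacetal
or ketone form is the cyclase substrate, so splitting it would assert
knowledge nobody has), and C38 hydroxylation (+O). Whether the final
hydroxylation requires only the oxadecalin (default) or the finished
tetrahydropyran is a configuration switch (`c38_requires`), because the
evidence does not settle it.

`simulate_pathway()` blocks a step when a required gene is knocked out or a
prerequisite is blocked; formula bookkeeping is exact integer arithmetic, so
the result is independent of application order for a fixed blocked set, and
blocked sets grow monotonically with the knockout set. The wild type ends at
C42H64O12; knocking out the oxadecalin cyclase gene (*mad10*) blocks the two
ring-forming steps and the ring-dependent C38 hydroxylation, ending at
C42H64O11 — 16 Da lighter, the Delta-mass signature by which the shunt
metabolite T-17 was recognised. Precursor-supply genes are modelled as
capability gates rather than chain reactions: knocking out the
methoxymalonate subcluster (e.g. the O-methyltransferase) starves the
extender and yields no product at all, but the redundant FkbH-like/ACP pools
(two of each in the cluster) tolerate single knockouts. Timing questions the
formula cannot see (possibly PKS-bound tetrahydrofuran formation) are
ignored, since all formula-level results are identical. The accumulated
intermediate of the tetrahydropyran-cyclase knockout was not observed
experimentally; the simulator reports its predicted formula with an
"unobserved" label.

## Mass-spectral diagnosis

Adduct m/z values are computed for the five packaged positive-mode species
([M+H]+, [M+Na]+, [M+NH4]+ and the one- and two-water-loss ions), electron
mass included. Average masses are the default because the printed spectrum
values are unit-resolution ion-trap observations: neither average nor
monoisotopic masses reproduce them exactly, so every comparison against
printed ions is tolerance-based (default 0.5 Da) and never exact.
`diagnose_delta()` assigns the reference spectrum to the reference formula's
adducts, takes the modal integer shift to the unknown spectrum (ties broken
toward the smallest absolute shift), interprets it through a small loss
table (−16 absent hydroxyl, −18 dehydration, −14 demethylation, +16 added
hydroxyl), proposes a formula, and confirms by re-matching. An inconsistent
shift yields an "undiagnosed" result, not an exception.

One printed tetromadurin ion (the [M+H−H2O]+ value, 739.84) is mutually
inconsistent with the other printed ions of the same pair of compounds
(~4 Da below the value implied by them); the packaged peak-list fixture
transcribes it as printed with a provenance comment, and the corresponding
matching test documents the discrepancy rather than hiding it.

## The synthetic-data generator

`make_cluster()` turns an architecture spec into sequences by planting the
declared motif residues at the scaffold anchor columns and applying seeded
neutral substitutions to 10% of the remaining positions (never within two
residues of an anchor, so ground truth stays valid; a KR NADPH-site deletion
is realised as the literal removal of the window). This emulates the
divergence the annotator must tolerate, but deliberately not real
phylogenetic structure: substitutions are uniform rather than
BLOSUM-weighted, there are no insertions outside the modelled deletion, and
inter-domain linkers are absent. Passing the blind-recovery tests therefore
shows the anchor logic is correct and robust to uniform divergence — not
that the annotator would segment raw, unannotated PKS proteins (profile-HMM
detection is explicitly out of scope; inputs arrive pre-split by a module
map). Degradation behaviour is part of the contract: recovery is exact up to
20% substitution, and at saturating divergence the aligner refuses
("unalignable domain") rather than miscalling.

Nucleotide templates for the deletion-screening arithmetic are seeded random
sequences at 70% GC (actinomycete-like) with planted primer footprints;
synthetic peak lists place one peak per adduct with seeded Gaussian m/z
noise and log-uniform intensities.

## Problem sizes and determinism

The packaged mad fixture (seed 42) has 15 modules / 65 domains. The
property suites run 100 random architectures for blind recovery, 200 random
chains for SMILES-vs-bookkeeping formula conservation (cross-checked against
Open Babel as an independent oracle), and 30 seeded noisy spectra for the
round-trip diagnosis — sizes chosen to exercise every rule combination while
keeping the default suite comfortably interactive. All randomness flows
through explicit seeds; regenerating any fixture with the same (spec, seed)
is byte-identical, and the end-to-end pipeline writes byte-identical reports
on rerun.

## Known limitations

* Trans-AT PKSs, NRPS condensation logic and iterative modules are out of
  scope; the annotator assumes one cis-AT module inventory per extension.
* Domain segmentation is input, not inference.
* The SMILES writer emits connectivity only (stereo lives in a sidecar
  annotation); conformers and double-bond migration chemistry are not
  modelled.
* Production levels, retention times and UV maxima are wet-lab observables
  outside what sequence-level bookkeeping can reproduce; the package stores
  such values only as fixture metadata.
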