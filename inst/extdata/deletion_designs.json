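{
  "comment": [
    "In-frame deletion designs and printed screening-amplicon sizes for the",
    "two mad cyclase knockouts and the tetronomycin-cluster homologue tmn8.",
    "The mad31 legend prints 'PCR product size Delta-tsn15 mutant: 689 bp'",
    "where context implies Delta-mad31; transcribed as printed in notes."
  ],
  "designs": [
    {"gene_id": "mad10", "gene_cds_length_nt": 1404, "deleted_length_nt": 906,
     "wt_amplicon_nt": 1913,
     "notes": "906/1404 bp deleted; WT screening product 1913 bp"},
    {"gene_id": "mad31", "gene_cds_length_nt": 561, "deleted_length_nt": 291,
     "wt_amplicon_nt": 980,
     "notes": "291/561 bp deleted; WT screening product 980 bp; legend prints 'Delta-tsn15 mutant: 689 bp' (as printed)"},
    {"gene_id": "tmn8", "gene_cds_length_nt": 573, "deleted_length_nt": 573,
     "wt_amplicon_nt": 971,
     "notes": "entire 573 bp coding frame deleted; WT screening product 971 bp"}
  ]
}
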