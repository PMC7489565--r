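{
  "cluster_id": "mad",
  "comment": [
    "Architecture of the tetromadurin (mad) biosynthetic gene cluster of",
    "Actinomadura verrucosospora: 7 PKS multienzymes (madAI-madAVII) carrying",
    "one loading module (KS^Q, hybrid HASH AT) and 14 extension modules, plus",
    "the 25 tailoring/accessory genes with their functional labels.",
    "Module-to-protein split: AI(LM,1,2) AII(3,4) AIII(5,6) AIV(7,8)",
    "AV(9,10,11) AVI(12,13) AVII(14).",
    "Per-module acetate/propionate assignments: modules 4, 7, 11, 12 are",
    "propionate (published alpha-methyl and ER stereochemistry arguments),",
    "module 13 is the methoxymalonate position (YASH motif, resolved by the",
    "cluster-level override), modules 2, 5 and 8 are acetate (their ER/alpha",
    "positions are not listed among the stereo-relevant methyls). The",
    "remaining split (3 vs 1, 6 vs 5, 9 vs 10) is inferred from the",
    "side-methyl carbon numbering (C32-C38 ascend along the chain) and the",
    "published 6-acetate/8-propionate/1-methoxymalonate precursor tally;",
    "propionate was placed at 3, 6 and 9.",
    "DH domains are present in modules 1-6 and 8-13 (absent in 7 and 14);",
    "module 5's DH lacks the YGP tyrosine (inactive). KR domains are present",
    "in all 14 extension modules; KR 12 and 14 lack the catalytic tyrosine",
    "and KR 12 additionally carries the NADPH-site deletion. ER domains sit",
    "in modules 2, 4, 8, 11; those of 4 and 11 lack the key tyrosine",
    "(D-configuring); 2 and 8 are modelled L-configuring (inconsequential:",
    "both are acetate modules)."
  ],
  "genes": [
    {"gene_id": "mad1",  "product_label": "regulator"},
    {"gene_id": "mad2",  "product_label": "regulator"},
    {"gene_id": "mad3",  "product_label": "other"},
    {"gene_id": "mad4",  "product_label": "other"},
    {"gene_id": "mad6",  "product_label": "other"},
    {"gene_id": "mad7",  "product_label": "FkbH-like"},
    {"gene_id": "mad8",  "product_label": "ACP"},
    {"gene_id": "madB",  "product_label": "epoxide-hydrolase"},
    {"gene_id": "madC",  "product_label": "epoxidase"},
    {"gene_id": "mad10", "product_label": "PyrE3-like-cyclase", "cds_length_nt": 1404},
    {"gene_id": "mad11", "product_label": "dehydrogenase"},
    {"gene_id": "mad12", "product_label": "ACP"},
    {"gene_id": "mad13", "product_label": "dehydrogenase"},
    {"gene_id": "mad14", "product_label": "FkbH-like"},
    {"gene_id": "mad15", "product_label": "O-methyltransferase"},
    {"gene_id": "mad16", "product_label": "FabH-like"},
    {"gene_id": "mad17", "product_label": "acyltransferase(Agg4-like)"},
    {"gene_id": "mad18", "product_label": "dehydratase(Agg5-like)"},
    {"gene_id": "mad20", "product_label": "other"},
    {"gene_id": "mad25", "product_label": "transporter"},
    {"gene_id": "mad26", "product_label": "transporter"},
    {"gene_id": "mad27", "product_label": "regulator"},
    {"gene_id": "mad29", "product_label": "P450"},
    {"gene_id": "mad30", "product_label": "P450"},
    {"gene_id": "mad31", "product_label": "VstJ-like-cyclase", "cds_length_nt": 561},
    {"gene_id": "madAI",   "product_label": "PKS"},
    {"gene_id": "madAII",  "product_label": "PKS"},
    {"gene_id": "madAIII", "product_label": "PKS"},
    {"gene_id": "madAIV",  "product_label": "PKS"},
    {"gene_id": "madAV",   "product_label": "PKS"},
    {"gene_id": "madAVI",  "product_label": "PKS"},
    {"gene_id": "madAVII", "product_label": "PKS"}
  ],
  "modules": [
    {"module_index": "LM", "gene_id": "madAI",
     "domains": {"KS": {"cat_residue": "Q"}, "AT": {"motif": "HASH"}, "ACP": {}}},
    {"module_index": 1, "gene_id": "madAI",
     "domains": {"KS": {}, "AT": {"motif": "HAFH"},
                 "DH": {}, "KR": {}, "ACP": {}}},
    {"module_index": 2, "gene_id": "madAI",
     "domains": {"KS": {}, "AT": {"motif": "TAFH"},
                 "DH": {}, "ER": {"key_tyr": true}, "KR": {}, "ACP": {}}},
    {"module_index": 3, "gene_id": "madAII",
     "domains": {"KS": {}, "AT": {"motif": "YASH"},
                 "DH": {}, "KR": {}, "ACP": {}}},
    {"module_index": 4, "gene_id": "madAII",
     "domains": {"KS": {}, "AT": {"motif": "VASH"},
                 "DH": {}, "ER": {"key_tyr": false}, "KR": {}, "ACP": {}}},
    {"module_index": 5, "gene_id": "madAIII",
     "domains": {"KS": {}, "AT": {"motif": "VAFH"},
                 "DH": {"ygp_tyr": false}, "KR": {}, "ACP": {}}},
    {"module_index": 6, "gene_id": "madAIII",
     "domains": {"KS": {}, "AT": {"motif": "WASH"},
                 "DH": {}, "KR": {}, "ACP": {}}},
    {"module_index": 7, "gene_id": "madAIV",
     "domains": {"KS": {}, "AT": {"motif": "YASH"},
                 "KR": {}, "ACP": {}}},
    {"module_index": 8, "gene_id": "madAIV",
     "domains": {"KS": {}, "AT": {"motif": "HAFH"},
                 "DH": {}, "ER": {"key_tyr": true}, "KR": {}, "ACP": {}}},
    {"module_index": 9, "gene_id": "madAV",
     "domains": {"KS": {}, "AT": {"motif": "YASH"},
                 "DH": {}, "KR": {}, "ACP": {}}},
    {"module_index": 10, "gene_id": "madAV",
     "domains": {"KS": {}, "AT": {"motif": "YAFH"},
                 "DH": {}, "KR": {}, "ACP": {}}},
    {"module_index": 11, "gene_id": "madAV",
     "domains": {"KS": {}, "AT": {"motif": "VASH"},
                 "DH": {}, "ER": {"key_tyr": false}, "KR": {}, "ACP": {}}},
    {"module_index": 12, "gene_id": "madAVI",
     "domains": {"KS": {}, "AT": {"motif": "YASH"},
                 "DH": {}, "KR": {"cat_tyr": false, "nadph_deletion": true},
                 "ACP": {}}},
    {"module_index": 13, "gene_id": "madAVI",
     "domains": {"KS": {}, "AT": {"motif": "YASH"},
                 "DH": {}, "KR": {}, "ACP": {}}},
    {"module_index": 14, "gene_id": "madAVII",
     "domains": {"KS": {}, "AT": {"motif": "HAFH"},
                 "KR": {"cat_tyr": false}, "ACP": {}}}
  ]
}
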