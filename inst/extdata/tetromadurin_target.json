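{
  "notes": [
    "Retrobiosynthetic decomposition of the linear tetromadurin backbone",
    "(the target-derived chain): propionate starter + 14 extensions,",
    "totalling 6 acetate, 8 propionate and 1 methoxymalonate units.",
    "Extension i carries the beta-carbon state C(2*(14-i)+3) its module's",
    "reductive domains produce; position 12's beta carbon is C7, which",
    "bears a D-hydroxyl in the final structure. Double-bond placement",
    "(C5-C6, C10-C11, C12-C13) follows the partially cyclised tetronasin",
    "intermediate."
  ],
  "starter": {"extender": "propionate"},
  "extensions": [
    {"position": 1, "extender": "acetate", "beta_state": "enoyl_double_bond"},
    {"position": 2, "extender": "acetate", "beta_state": "methylene"},
    {"position": 3, "extender": "propionate", "beta_state": "enoyl_double_bond",
     "alpha_substituent": "methyl"},
    {"position": 4, "extender": "propionate", "beta_state": "methylene",
     "alpha_substituent": "methyl", "alpha_stereo": "D"},
    {"position": 5, "extender": "acetate", "beta_state": "hydroxyl",
     "beta_stereo": "D"},
    {"position": 6, "extender": "propionate", "beta_state": "enoyl_double_bond",
     "alpha_substituent": "methyl"},
    {"position": 7, "extender": "propionate", "beta_state": "hydroxyl",
     "beta_stereo": "D", "alpha_substituent": "methyl", "alpha_stereo": "D"},
    {"position": 8, "extender": "acetate", "beta_state": "methylene"},
    {"position": 9, "extender": "propionate", "beta_state": "enoyl_double_bond",
     "alpha_substituent": "methyl"},
    {"position": 10, "extender": "acetate", "beta_state": "enoyl_double_bond"},
    {"position": 11, "extender": "propionate", "beta_state": "methylene",
     "alpha_substituent": "methyl", "alpha_stereo": "D"},
    {"position": 12, "extender": "propionate", "beta_state": "hydroxyl",
     "beta_stereo": "D", "alpha_substituent": "methyl", "alpha_stereo": "D"},
    {"position": 13, "extender": "methoxymalonate",
     "beta_state": "enoyl_double_bond", "alpha_substituent": "methoxy"},
    {"position": 14, "extender": "acetate", "beta_state": "ketone"}
  ]
}
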