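{
  "version": "1.0",
  "note": "Synthetic consensus scaffolds built from the published motif descriptions; anchor columns are a package convention, not literature alignment coordinates.",
  "scaffolds": {
    "KS": {
      "sequence": "NKDEESTHMHMAVVAENMCDRTKGMLPEHLISHRYYCYDLNSSKYMETWHHQSKYGPSVTVDTACSSSLVAKTVIMTAPSLSIERCRCWPAKQTTKQYGYLVRYGKPNTYVEAHGTGTMLYRQVVDEHTDGDFYRPTYCWKGLQPIWFKSNIGHLEDRETHGARLDHQDLDIYCTFNICFTGNAKQWVHFNYAEWM",
      "anchors": {
        "cat_cys": 65,
        "his1": 114,
        "his2": 154
      }
    },
    "AT": {
      "sequence": "AHHPIWASQDFVSCVSMMYKGPVRHYVNFLLLDDCLHTNHKGHFEKRAAIGHSQGEMYIRMQHIIKPDLNRSVAGDMPHQSGAILMMFTYGYASHQSKFEYIWSINCPIRESIRHMWTLNIVILILYFLKDHYYQKNFIY",
      "anchors": {
        "motif": [92, 95]
      }
    },
    "DH": {
      "sequence": "HAYNWKSGKWDTYIDVFCTYVECTSGYYRFKFEVKNKYVSFAYGPATLMVPHARANGKNQHWRMCTLEKVFWGSYQAENDMPTFWPHHPALLDAALGHERRTKFWQQYEIVPLQFCCIICQLEHPDNQARSEIDMSAQCLQ",
      "anchors": {
        "ygp_tyr": 43,
        "cat_asp": 93
      }
    },
    "KR": {
      "sequence": "NPNKFAHGEHRCQDEYMKQLAEQAFRWVSAGRRGLGGTVLDDAWRAKRDPNHFWWLQVHGMWTLIWFNHLWLGAVQQKVDVGGTKQKWRTLKKRQWRKSVAYSANAQCEVLVKYQFKYIWRCMKDYHFQVVLHKTMMQWQ",
      "anchors": {
        "nadph": [31, 43],
        "ldd": [40, 42],
        "cat_tyr": 102,
        "tyr_plus2": 104
      }
    },
    "ER": {
      "sequence": "LTKWMMPATTAVSYRRNNAAPCVGLLAKCFWAYMLVDCFFYLWKFMERYCCCCFVVYRKWGTAYAGLACKKTNSVHQGIIICAWVMSYKHFWHTFYTMKICFSGNLIFRFHNRAWRNDYGWEERSSIAFYFRMVTRQ",
      "anchors": {
        "key_tyr": 64
      }
    },
    "ACP": {
      "sequence": "PMTSSWMHPPPCNMGFDVKIVLIVHNKCFIGLDSLDIKILMRWPPYIRSQYCLIFQQCVSIRSQPPHGYHYFFEAR",
      "anchors": {
        "ppant_ser": 34
      }
    }
  }
}
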