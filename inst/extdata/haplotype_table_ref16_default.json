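{
  "version": "table-ref16-default",
  "comment": "Five-site cut(+)/uncut(-) patterns over the loci XmnI_5Gg, HindIII_Gg, HindIII_Ag, HincII_3psb, HinfI_5b. The classical patterns and the five named atypical subtype patterns are versioned configuration: the primary literature defers the exact site tables to supplementary material, so analyses bind the generator and the classifier to one and the same table.",
  "loci": ["XmnI_5Gg", "HindIII_Gg", "HindIII_Ag", "HincII_3psb", "HinfI_5b"],
  "classical": {
    "Benin": "----+",
    "Bantu": "-+---",
    "Senegal": "++-++",
    "Cameroon": "-++-+",
    "Arab-Indian": "++-+-"
  },
  "atypical": {
    "atypical-I": "+---+",
    "atypical-II": "--+-+",
    "atypical-III": "+-+--",
    "atypical-IV": "---++",
    "atypical-V": "+++++"
  }
}
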