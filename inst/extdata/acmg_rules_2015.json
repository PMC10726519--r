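{
  "name": "acmg_amp_2015",
  "description": "Standard 2015 ACMG/AMP evidence combining rules (Richards et al., Genet Med 2015). Patterns are matched on counts of effective strengths with at-least semantics: vs = very strong (pathogenic), s = strong, m = moderate, p = supporting; ba = stand-alone benign, bs = strong benign, bp = supporting benign.",
  "pathogenic": [
    {"rule": "2 very strong", "vs": 2},
    {"rule": "1 very strong + 1 strong", "vs": 1, "s": 1},
    {"rule": "1 very strong + 2 moderate", "vs": 1, "m": 2},
    {"rule": "1 very strong + 1 moderate + 1 supporting", "vs": 1, "m": 1, "p": 1},
    {"rule": "1 very strong + 2 supporting", "vs": 1, "p": 2},
    {"rule": "2 strong", "s": 2},
    {"rule": "1 strong + 3 moderate", "s": 1, "m": 3},
    {"rule": "1 strong + 2 moderate + 2 supporting", "s": 1, "m": 2, "p": 2},
    {"rule": "1 strong + 1 moderate + 4 supporting", "s": 1, "m": 1, "p": 4}
  ],
  "likely_pathogenic": [
    {"rule": "1 very strong + 1 moderate", "vs": 1, "m": 1},
    {"rule": "1 strong + 1 moderate", "s": 1, "m": 1},
    {"rule": "1 strong + 2 supporting", "s": 1, "p": 2},
    {"rule": "3 moderate", "m": 3},
    {"rule": "2 moderate + 2 supporting", "m": 2, "p": 2},
    {"rule": "1 moderate + 4 supporting", "m": 1, "p": 4}
  ],
  "benign": [
    {"rule": "1 stand-alone", "ba": 1},
    {"rule": "2 strong benign", "bs": 2}
  ],
  "likely_benign": [
    {"rule": "1 strong benign + 1 supporting benign", "bs": 1, "bp": 1},
    {"rule": "2 supporting benign", "bp": 2}
  ]
}
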