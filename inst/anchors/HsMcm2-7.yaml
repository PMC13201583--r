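# Interface residue anchors for human Mcm2-7 (see ScMcm2-7.yaml for the
# anchor semantics and ring direction convention).
set_name: HsMcm2-7
numbering: author
ring_order: [Mcm2, Mcm6, Mcm4, Mcm7, Mcm3, Mcm5]
subunits:
  Mcm2: {walkerA_pro: 525, argfinger_minus4: 652, h2i_leu: 556, ps1b_lys: 613}
  Mcm3: {walkerA_pro: 347, argfinger_minus4: 474, h2i_leu: 378, ps1b_lys: 435}
  Mcm4: {walkerA_pro: 512, argfinger_minus4: 639, h2i_leu: 543, ps1b_lys: 600}
  Mcm5: {walkerA_pro: 383, argfinger_minus4: 509, h2i_leu: 414, ps1b_lys: 471}
  Mcm6: {walkerA_pro: 398, argfinger_minus4: 525, h2i_leu: 429, ps1b_lys: 486}
  Mcm7: {walkerA_pro: 383, argfinger_minus4: 510, h2i_leu: 414, ps1b_lys: 471}
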