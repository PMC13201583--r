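# Interface residue anchors for S. cerevisiae Mcm2-7, derived by alignment
# to the archaeal 152-residue AAA+ core.  Each subunit contributes its
# Walker-A proline and h2i leucine on one interface face, and the
# arginine-finger-minus-4 residue and ps1-beta lysine on the other.
# The OB/core residue spans of the eukaryotic subunits are not shipped;
# template-based runs require a user-supplied correspondence.
set_name: ScMcm2-7
numbering: author
ring_order: [Mcm2, Mcm6, Mcm4, Mcm7, Mcm3, Mcm5]
subunits:
  Mcm2: {walkerA_pro: 545, argfinger_minus4: 672, h2i_leu: 576, ps1b_lys: 633}
  Mcm3: {walkerA_pro: 411, argfinger_minus4: 538, h2i_leu: 442, ps1b_lys: 499}
  Mcm4: {walkerA_pro: 570, argfinger_minus4: 697, h2i_leu: 601, ps1b_lys: 658}
  Mcm5: {walkerA_pro: 418, argfinger_minus4: 545, h2i_leu: 449, ps1b_lys: 506}
  Mcm6: {walkerA_pro: 577, argfinger_minus4: 704, h2i_leu: 608, ps1b_lys: 665}
  Mcm7: {walkerA_pro: 462, argfinger_minus4: 589, h2i_leu: 493, ps1b_lys: 550}
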