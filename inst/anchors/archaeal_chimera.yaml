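# Residue anchors for the archaeal Sso-Pf chimeric MCM hexamer, in the
# deposited coordinate numbering (Sso N-domain keeps native numbers; Pf
# AAA+ numbers are offset by +1000).  `construct` carries the same anchors
# in native (construct) numbering.
set_name: archaeal_chimera
numbering: deposited
ring_order: [archaeal, archaeal, archaeal, archaeal, archaeal, archaeal]
subunits:
  archaeal:
    walkerA_pro: 1330        # Walker-A P-loop proline CA (ATP-site anchor)
    argfinger_minus4: 1824   # 4 residues before the arginine finger (T824)
    h2i_leu: 1361            # helix/horseshoe leucine of the h2i
    ps1b_lys: 1785           # conserved ps1-beta hairpin lysine
    ob_anchor: 201           # N-tier dihedral anchor (Sso P201)
    aaa_anchor: 1755         # C-tier dihedral anchor (Pf Y755)
    h2i_hydroxyl: 1357       # h2i serine whose hydroxyl binds a DNA phosphate
    h2i_amide: 1732          # h2i backbone amide that binds the next phosphate
    ps1b_amide: 1786         # ps1-beta backbone amide adjacent to the lysine
    ob_ranges: [[105, 130], [185, 265]]     # 107 residues, OB-fold
    core_ranges: [[1319, 1361], [1729, 1837]]  # 152-residue AAA+ core
    construct:
      walkerA_pro: 330
      argfinger_minus4: 824
      h2i_leu: 361
      ps1b_lys: 785
      ob_anchor: 201
      aaa_anchor: 755
      h2i_hydroxyl: 357
      h2i_amide: 732
      ps1b_amide: 786
      core_ranges: [[319, 361], [729, 837]]
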