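- subtype: H1.0
  peptide: YSDMIVAAIQAEK
  enzyme: trypsin
  start: 28
  end: 40
  missed_cleavages: 0
  labeled_residue: K
  labeled_position: 13
  precursor_charge: 2
  met_containing: yes
  lod_ng: 0.055
  loq_ng: 0.168
- subtype: H1.1
  peptide: KKPAGPSVSELIVQAASSSK
  enzyme: trypsin
  start: 37
  end: 56
  missed_cleavages: 1
  labeled_residue: K
  labeled_position: 20
  precursor_charge: 3
  met_containing: no
  lod_ng: 0.037
  loq_ng: 0.111
- subtype: H1.2
  peptide: TAPAAPAAAPPAE
  enzyme: glu_c
  start: 4
  end: 16
  missed_cleavages: 0
  labeled_residue: A
  labeled_position: 12
  precursor_charge: 2
  met_containing: no
  lod_ng: 0.026
  loq_ng: 0.08
- subtype: H1.3
  peptide: TAPLAPTIPAPAE
  enzyme: glu_c
  start: 4
  end: 16
  missed_cleavages: 0
  labeled_residue: L
  labeled_position: 4
  precursor_charge: 2
  met_containing: no
  lod_ng: 0.02
  loq_ng: 0.06
- subtype: H1.4
  peptide: TAPAAPAAPAPAE
  enzyme: glu_c
  start: 4
  end: 16
  missed_cleavages: 0
  labeled_residue: A
  labeled_position: 12
  precursor_charge: 2
  met_containing: no
  lod_ng: 0.032
  loq_ng: 0.098
- subtype: H1.5
  peptide: ATGPPVSELITK
  enzyme: trypsin
  start: 38
  end: 49
  missed_cleavages: 0
  labeled_residue: K
  labeled_position: 12
  precursor_charge: 2
  met_containing: no
  lod_ng: 0.046
  loq_ng: 0.14
- subtype: H1X
  peptide: ALVQNDTLLQVK
  enzyme: trypsin
  start: 95
  end: 106
  missed_cleavages: 0
  labeled_residue: K
  labeled_position: 12
  precursor_charge: 2
  met_containing: no
  lod_ng: 0.027
  loq_ng: 0.066
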