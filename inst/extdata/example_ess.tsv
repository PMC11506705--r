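peptide	ess	n_observations
YSDMIVAAIQAEK	0.93	1200
KKPAGPSVSELIVQAASSSK	0.41	45
TAPAAPAAAPPAE	0.38	60
TAPLAPTIPAPAE	0.44	80
TAPAAPAAPAPAE	0.35	52
ATGPPVSELITK	0.91	980
ALVQNDTLLQVK	0.89	640
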