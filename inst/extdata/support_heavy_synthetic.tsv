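fr_label	cdr_label	min_distance	interaction_class
38	52	4.05	proximal
40	53	4.10	proximal
48	50	3.80	hydrophobic
66	63	3.70	hydrophobic
66	65	3.90	hydrophobic
67	63	3.75	hydrophobic
67	65	3.85	hydrophobic
69	52	3.60	hydrophobic
71	55	3.70	hydrophobic
78	56	3.80	hydrophobic
82A	58	4.10	proximal
94	97	3.60	hydrophobic
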