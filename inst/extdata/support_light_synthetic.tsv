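fr_label	cdr_label	min_distance	interaction_class
3	26	4.00	proximal
60	50	4.10	proximal
63	54	3.00	hydrogen_bond
70	89	4.05	proximal
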