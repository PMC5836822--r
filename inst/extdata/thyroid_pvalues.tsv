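# Raw enrichment p-values for differentially expressed protein sets from
# papillary thyroid cancer experiments (dbDEPC: E39, E50, their intersection
# and union), tested over six interaction-type filters against an
# ANDSystem-style global network. One family of 24 tests; used to exercise
# Benjamini-Hochberg adjustment.
# experiment	type	p
E39	all_types	3.83E-03
E39	activity_and_transport_regulation	1.58E-01
E39	catalysis	6.56E-01
E39	coexpression	6.08E-01
E39	expression_regulation	7.27E-01
E39	interaction	4.62E-01
E50	all_types	2.02E-02
E50	activity_and_transport_regulation	1.09E-01
E50	catalysis	1.45E-05
E50	coexpression	5.00E-01
E50	expression_regulation	6.56E-01
E50	interaction	6.58E-02
E50_and_E39	all_types	4.36E-01
E50_and_E39	activity_and_transport_regulation	1.35E-01
E50_and_E39	catalysis	5.00E-01
E50_and_E39	coexpression	5.00E-01
E50_and_E39	expression_regulation	5.69E-01
E50_and_E39	interaction	7.84E-01
E50_or_E39	all_types	6.42E-06
E50_or_E39	activity_and_transport_regulation	4.03E-01
E50_or_E39	catalysis	1.11E-04
E50_or_E39	coexpression	1.19E-03
E50_or_E39	expression_regulation	8.89E-01
E50_or_E39	interaction	4.71E-02
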