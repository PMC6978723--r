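# galufer compound registry v1.
# Organic acids are the neutral, fully protonated species; phosphorylated
# intermediates carry the phosphoryl group as -PO3H (species = parent + HPO3).
# acetyl_coa is booked as its acetyl moiety at the oxidation level of acetate;
# the CoA thioester itself is handled as a cofactor pair, not an element pool.
id	name	formula
galacturonate	D-galacturonate	C6H10O7
tagaturonate	D-tagaturonate	C6H10O7
fructuronate	D-fructuronate	C6H10O7
mannonate	D-mannonate	C6H12O7
gluconate	D-gluconate	C6H12O7
kdg	2-keto-3-deoxygluconate	C6H10O6
kdpg	2-keto-3-deoxy-6-phosphogluconate	C6H11O9P
mannonate_6p	6-phosphomannonate	C6H13O10P
gluconate_6p	6-phosphogluconate	C6H13O10P
ribulose_5p	ribulose-5-phosphate	C5H11O8P
xylulose_5p	xylulose-5-phosphate	C5H11O8P
gap	glyceraldehyde-3-phosphate	C3H7O6P
bpg	1,3-bisphosphoglycerate	C3H8O10P2
pg3	3-phosphoglycerate	C3H7O7P
pg2	2-phosphoglycerate	C3H7O7P
pep	phosphoenolpyruvate	C3H5O6P
pyruvate	pyruvate	C3H4O3
lactate	lactate	C3H6O3
acetate	acetate	C2H4O2
acetyl_coa	acetyl-CoA (acetyl moiety)	C2H4O2
acetyl_p	acetyl-phosphate	C2H5O5P
co2	carbon dioxide	CO2
biomass	biomass (per C-mol)	CH1.8O0.5N0.2
water	water	H2O
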