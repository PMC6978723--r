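# Canonical galacturonate-isomerase (adapted Entner-Doudoroff) pathway,
# UxuE/UxuB/UxuA branch, run through lower glycolysis to lactate.
# Grammar: equation terms are registry compound ids with optional numeric
# coefficients; ATP / NADH / NADPH / NAD(P)H are cofactor tokens (net deltas
# of the phosphorylated / reduced member); H2O, H+ and inorganic phosphate
# are implicit closure species and never written. NAD(P)H resolves to the
# pathway's uxuB_cofactor option.
# substrate: galacturonate
# external: galacturonate lactate
id	enzyme	ec	equation	reversible	evidence
UxaC	uronate isomerase	5.3.1.12	galacturonate -> tagaturonate	TRUE	uxaC
UxuE	tagaturonate 3-epimerase	5.1.2.7	tagaturonate -> fructuronate	TRUE	uxaE
UxuB	fructuronate reductase	1.1.1.57	fructuronate + NAD(P)H -> mannonate	FALSE	uxuB
UxuA	mannonate dehydratase	4.2.1.8	mannonate -> kdg	FALSE	uxuA
KdgK	2-dehydro-3-deoxygluconokinase	2.7.1.45	kdg + ATP -> kdpg	FALSE	kdgK
KdgA	2-dehydro-3-deoxyphosphogluconate aldolase	4.1.2.14	kdpg -> pyruvate + gap	FALSE	kdgA
GAPDH	glyceraldehyde-3-phosphate dehydrogenase	1.2.1.12	gap -> bpg + NADH	FALSE	gapDH
PGK	phosphoglycerate kinase	2.7.2.3	bpg -> pg3 + ATP	TRUE	pgk
PGM	phosphoglycerate mutase	5.4.2.11	pg3 -> pg2	TRUE	pgam
ENO	enolase	4.2.1.11	pg2 -> pep	TRUE	eno
PYK	pyruvate kinase	2.7.1.40	pep -> pyruvate + ATP	FALSE	pyk
nLDH	D-/L-lactate dehydrogenase	1.1.1.27	pyruvate + NADH -> lactate	FALSE	ldh
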