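# Canonical isomerase pathway extended with the hypothetical
# PDH / phosphotransacetylase / acetate-kinase branch that would be required
# for the canonical route to co-produce acetate alongside lactate.
# substrate: galacturonate
# external: galacturonate lactate acetate co2
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
PDH	pyruvate dehydrogenase complex	1.2.4.1	pyruvate -> acetyl_coa + co2 + NADH	FALSE	pdh
PTA	phosphotransacetylase	2.3.1.8	acetyl_coa -> acetyl_p	TRUE	pta
AckA	acetate kinase	2.7.2.1	acetyl_p -> acetate + ATP	FALSE	ackA
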