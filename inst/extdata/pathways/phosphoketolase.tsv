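# Phosphoketolase pathway proper, entered at 6-phosphogluconate.
# substrate: gluconate_6p
# external: gluconate_6p lactate acetate co2
id	enzyme	ec	equation	reversible	evidence
GND	6-phosphogluconate dehydrogenase (decarboxylating)	1.1.1.44	gluconate_6p -> ribulose_5p + co2 + NADPH	FALSE	6pgd
RPE	ribulose-5-phosphate 3-epimerase	5.1.3.1	ribulose_5p -> xylulose_5p	TRUE	araD
XpkA	xylulose-5-phosphate phosphoketolase	4.1.2.9	xylulose_5p -> gap + acetyl_p	FALSE	xpkA
GAPDH	glyceraldehyde-3-phosphate dehydrogenase	1.2.1.12	gap -> bpg + NADH	FALSE	gapDH
PGK	phosphoglycerate kinase	2.7.2.3	bpg -> pg3 + ATP	TRUE	pgk
PGM	phosphoglycerate mutase	5.4.2.11	pg3 -> pg2	TRUE	pgam
ENO	enolase	4.2.1.11	pg2 -> pep	TRUE	eno
PYK	pyruvate kinase	2.7.1.40	pep -> pyruvate + ATP	FALSE	pyk
nLDH	D-/L-lactate dehydrogenase	1.1.1.27	pyruvate + NADH -> lactate	FALSE	ldh
AckA	acetate kinase	2.7.2.1	acetyl_p -> acetate + ATP	FALSE	ackA
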