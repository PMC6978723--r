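# Gene -> protein evidence map for the L. suebicus LCV1 pathway reactions.
# Paralogs are semicolon-separated; a reaction is covered when any paralog is
# detected. The two novel activities (mannonate kinase, 6-phosphomannonate
# 2-epimerase) are candidate-tier: their structural genes are unresolved, the
# listed proteins are gluconate-kinase homologs / the epimerase candidate,
# and they are reported but never counted toward completeness.
evidence_key	tier	proteins
uxaC	confirmed	A0A0R1WA62;A0A0R1WAR4
uxaE	confirmed	A0A0R1W3Z7
uxuB	confirmed	A0AR1W2X9
uxuA	confirmed	UXUA_UNDETECTED
kdgK	confirmed	KDGK_UNDETECTED
kdgA	confirmed	KDGA_UNDETECTED
6pgd	confirmed	A0A0R1WAU7
gntK	confirmed	A0A0R1W2R7;A0A0R1W6K8
araD	confirmed	A0A0R1W2Q5
xpkA	confirmed	A0AR1W2X8
gapDH	confirmed	A0A0R1WD78;A0A0R1W347
pgk	confirmed	A0A0R1W7B1
pgam	confirmed	A0A0R1WBW2;A0A0R1W3N5;A0A0R1W8P2;A0A0R1W2R9;A0A0R1W2L2;A0A0R1VYX3;A0A0R1W2D7
eno	confirmed	A0A0R1W6P1
pyk	confirmed	A0A0R1W3H0
ldh	confirmed	A0AR1W2X2;A0A0R1W2M1
pdh	confirmed	A0A0R1W4W0;A0A0R1W442;A0A0R1W4J5;A0A0R1WEK4
pta	confirmed	A0A0R1W6L8
ackA	confirmed	A0A0R1VTZ1
pntAB	confirmed	A0A0R1W642;A0A0R1WE53;A0A0R1W6T3
nox	confirmed	A0A0R1WBZ1
mannonate_kinase	candidate	A0A0R1W2R7;A0A0R1W6K8
pmannonate_epimerase	candidate	A0A0R1W1H9
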