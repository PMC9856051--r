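ligand	receptor	source
IL1A	IL1R1	HGNC-interleukin
IL1B	IL1R1	HGNC-interleukin
IL1RN	IL1R1	HGNC-interleukin
IL2	IL2RA	HGNC-interleukin
IL2	IL2RB	HGNC-interleukin
IL2	IL2RG	HGNC-interleukin
IL3	IL3RA	HGNC-interleukin
IL4	IL4R	HGNC-interleukin
IL5	IL5RA	HGNC-interleukin
IL6	IL6R	HGNC-interleukin
IL7	IL7R	HGNC-interleukin
IL7	IL2RG	HGNC-interleukin
IL9	IL9R	HGNC-interleukin
IL10	IL10RA	HGNC-interleukin
IL10	IL10RB	HGNC-interleukin
IL11	IL11RA	HGNC-interleukin
IL12A	IL12RB1	HGNC-interleukin
IL12A	IL12RB2	HGNC-interleukin
IL12B	IL12RB1	HGNC-interleukin
IL12B	IL12RB2	HGNC-interleukin
IL13	IL13RA1	HGNC-interleukin
IL13	IL13RA2	HGNC-interleukin
IL15	IL15RA	HGNC-interleukin
IL17A	IL17RA	HGNC-interleukin
IL17F	IL17RA	HGNC-interleukin
IL18	IL18R1	HGNC-interleukin
IL18	IL18RAP	HGNC-interleukin
IL21	IL21R	HGNC-interleukin
IL22	IL22RA1	HGNC-interleukin
IL22	IL22RA2	HGNC-interleukin
IL23A	IL23R	HGNC-interleukin
IL24	IL20RA	HGNC-interleukin
IL25	IL17RB	HGNC-interleukin
IL26	IL20RA	HGNC-interleukin
IL27	IL27RA	HGNC-interleukin
IL33	IL1RL1	literature-review
IL34	CSF1R	literature-review
IL36A	IL1RL2	HGNC-interleukin
IL36B	IL1RL2	HGNC-interleukin
IL36G	IL1RL2	HGNC-interleukin
IL37	IL18R1	literature-review
IFNA1	IFNAR1	HGNC-interferon
IFNA1	IFNAR2	HGNC-interferon
IFNA2	IFNAR1	HGNC-interferon
IFNB1	IFNAR1	HGNC-interferon
IFNB1	IFNAR2	HGNC-interferon
IFNG	IFNGR1	HGNC-interferon
IFNG	IFNGR2	HGNC-interferon
IFNL1	IFNLR1	HGNC-interferon
IFNL2	IFNLR1	HGNC-interferon
IFNL3	IFNLR1	HGNC-interferon
TNF	TNFRSF1A	literature-review
TNF	TNFRSF1B	literature-review
TGFB1	TGFBR1	literature-review
TGFB1	TGFBR2	literature-review
GAS6	AXL	interaction-database
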