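id	x	y	z	radius	network
node01	36	-8	32	5	left_language
node02	-60	16	32	5	left_language
node03	12	-56	8	5	left_language
node04	-12	-56	-16	5	left_language
node05	-12	-32	-40	5	right_homologue
node06	-12	40	-40	5	right_homologue
node07	36	-32	32	5	right_homologue
node08	60	-80	56	5	default
node09	60	40	8	5	default
node10	-12	16	56	5	default
node11	60	-56	8	5	default
node12	-36	40	8	5	default
node13	-36	-56	56	5	default
node14	-12	-80	32	5	visual
node15	36	-80	-40	5	visual
node16	-60	-32	8	5	visual
node17	36	-56	-40	5	visual
node18	-60	-8	8	5	visual
node19	-60	40	32	5	salience
node20	-12	-80	56	5	salience
node21	-60	-80	32	5	salience
node22	12	-80	56	5	salience
node23	-60	40	8	5	excluded
node24	-12	-8	32	5	excluded
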