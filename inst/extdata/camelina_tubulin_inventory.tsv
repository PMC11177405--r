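# Tubulin gene inventory of the Camelina sativa DH55 reference genome
# (NCBI assembly GCA_000633955.1), transcribed from the published catalogue.
name	ncbi_gene_id	gene_length_bp	exons	peptide_length_aa	isotype	class	chromosome	subgenome	status	family
CsTUA2-A	104742538	2266	4	450	TUA2	I	14	G1	functional	TUA
CsTUA2-B	104777925	2266	4	450	TUA2	I	3	G2	functional	TUA
CsTUA2-C	104758270	2138	4	450	TUA2	I	17	G3	functional	TUA
CsTUA4-A	104765838	2219	4	451	TUA4	I	19	G1	functional	TUA
CsTUA4-B	104784567	2193	4	451	TUA4	I	1	G2	functional	TUA
CsTUA4-C	104746364	2246	4	451	TUA4	I	15	G3	functional	TUA
CsTUA6-A	104703779	2267	4	450	TUA6	I	7	G1	functional	TUA
CsTUA6-B	104752837	8668	4	450	TUA6	I	16	G2	functional	TUA
CsTUA6-C	104714511	2598	4	450	TUA6	I	9	G3	functional	TUA
CsTUA1-A	104700952	2319	5	450	TUA1	II	7	G1	functional	TUA
CsTUA1-Un	104773561	5961	5	444	TUA1	II	Scaff00574	unplaced	functional	TUA
CsTUA3-A	104706313	2150	5	450	TUA3	II	8	G1	functional	TUA
CsTUA3-B	104736043	2041	5	450	TUA3	II	13	G2	functional	TUA
CsTUA3-C	104770349	2079	5	450	TUA3	II	20	G3	functional	TUA
CsTUA5p-A	104706312	840	NA	NA	TUA5	II	8	G1	pseudogene	TUA
CsTUA5-B	104736047	2114	5	450	TUA5	II	13	G2	functional	TUA
CsTUA5-C	104770351	2052	5	450	TUA5	II	20	G3	functional	TUA
CsTUB6-A	104705499	2440	3	449	TUB6	I	8	G1	functional	TUB
CsTUB6-B	104735240	2488	3	449	TUB6	I	13	G2	functional	TUB
CsTUB6-C	104769465	2401	3	449	TUB6	I	20	G3	functional	TUB
CsTUB2-A	104780498	2355	3	449	TUB2	II	4	G1	functional	TUB
CsTUB2-B	104790913	2341	3	450	TUB2	II	6	G2	functional	TUB
CsTUB2-C	104711158	1989	3	450	TUB2	II	9	G3	functional	TUB
CsTUB3-A	104726871	2365	3	450	TUB3	II	11	G1	functional	TUB
CsTUB3-B	104762402	2080	3	451	TUB3	II	18	G2	functional	TUB
CsTUB3-C	104740363	2279	3	451	TUB3	II	2	G3	functional	TUB
CsTUB7-A	104700544	2319	3	449	TUB7	II	7	G1	functional	TUB
CsTUB7-B	104749926	2242	3	448	TUB7	II	16	G2	functional	TUB
CsTUB7-C	104786727	3249	3	449	TUB7	II	5	G3	functional	TUB
CsTUB8-A	104706681	1901	3	449	TUB8	II	8	G1	functional	TUB
CsTUB8-B	104736398	1827	3	449	TUB8	II	13	G2	functional	TUB
CsTUB4-C	104771594	3032	3	444	TUB4	III	20	G3	functional	TUB
CsTUB9-A	104722972	1878	3	444	TUB9	III	11	G1	functional	TUB
CsTUB9-B	104718249	1926	3	444	TUB9	III	10	G2	functional	TUB
CsTUB9-C	104731465	1892	3	444	TUB9	III	12	G3	functional	TUB
CsTUB1-A	104702324	2521	3	448	TUB1	IV	7	G1	functional	TUB
CsTUB1-B	104751460	2502	3	448	TUB1	IV	16	G2	functional	TUB
CsTUB5-A	104740697	2660	3	449	TUB5	IV	14	G1	functional	TUB
CsTUB5-B	104776116	3217	3	449	TUB5	IV	3	G2	functional	TUB
CsTUB5-C	104756348	3828	3	450	TUB5	IV	17	G3	functional	TUB
CsTUB-A	104781875	2245	3	446	TUB10	III-like	4	G1	functional	TUB
CsTUB-B	104792233	2427	3	446	TUB10	III-like	6	G2	functional	TUB
CsTUB-C	104786080	2352	3	446	TUB10	III-like	5	G3	functional	TUB
CsTUB1p-C	NA	NA	NA	NA	TUB1	IV	NA	G3	pseudogene	TUB
CsTUB3p-C	NA	NA	NA	NA	TUB3	II	2	G3	pseudogene	TUB
CsTUB4p-A	NA	NA	NA	NA	TUB4	III	NA	G1	pseudogene	TUB
CsTUB4p-B	NA	NA	NA	NA	TUB4	III	NA	G2	pseudogene	TUB
CsTUB4p-C	NA	NA	NA	NA	TUB4	III	NA	G3	pseudogene	TUB
CsTUB9p-A	NA	NA	NA	NA	TUB9	III	NA	G1	pseudogene	TUB
CsTUB9p-B	NA	NA	NA	NA	TUB9	III	NA	G2	pseudogene	TUB
CsTUB9p-C	NA	NA	NA	NA	TUB9	III	NA	G3	pseudogene	TUB
CsTUG1-A	104699727	3344	10	474	TUG1	1	7	G1	functional	TUG
CsTUG1-B	104749225	3194	10	474	TUG1	1	16	G2	functional	TUG
CsTUG1-C	104788465	3135	10	474	TUG1	1	5	G3	functional	TUG
CsTUG2-A	104708550	2813	10	474	TUG2	2	8	G1	functional	TUG
CsTUG2-B	104734567	2835	10	474	TUG2	2	13	G2	functional	TUG
CsTUG2-C	104768758	2737	10	474	TUG2	2	20	G3	functional	TUG
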