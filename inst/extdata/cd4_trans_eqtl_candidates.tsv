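module	snp_id	gene_id	snp_chrom	snp_pos	gene_chrom	gene_start	gene_end	beta	p_value	p_fdr
M9	rs9293162	FCER1A	chr5	25065470	chr1	159253678	159278014	1.851	1.1927e-07	0.077
M9	rs978897	FCER1A	chr7	15598156	chr1	159253678	159278014	1.670	3.2865e-07	0.094
M12	rs3862556	KIAA0101	chr10	76540987	chr15	64657210	64673702	-0.924	2.4332e-08	0.046
M12	rs711114	KIAA0101	chr12	78003541	chr15	64657210	64673702	-0.848	5.0807e-08	0.048
M12	rs10283761	BIRC5	chr9	26755930	chr17	76210276	76221716	-0.345	5.3493e-08	0.048
M12	rs9561023	KIAA0101	chr13	93022401	chr15	64657210	64673702	-0.999	6.0208e-08	0.048
M12	rs2513046	KIAA0101	chr11	62236094	chr15	64657210	64673702	-0.999	6.0208e-08	0.048
M12	rs17009383	KIAA0101	chr3	21771769	chr15	64657210	64673702	-0.573	7.3813e-08	0.048
M12	rs4806933	KIAA0101	chr19	3414020	chr15	64657210	64673702	-0.727	1.6853e-07	0.079
M12	rs4745758	KIAA0101	chr10	76568257	chr15	64657210	64673702	-0.814	4.7989e-07	0.095
M12	rs11001178	KIAA0101	chr10	76601805	chr15	64657210	64673702	-0.814	4.7989e-07	0.095
M12	rs10824245	KIAA0101	chr10	76666799	chr15	64657210	64673702	-0.814	4.7989e-07	0.095
M12	rs736086	KIAA0101	chr10	76683785	chr15	64657210	64673702	-0.814	4.7989e-07	0.095
M12	rs4746248	KIAA0101	chr10	76705881	chr15	64657210	64673702	-0.814	4.7989e-07	0.095
M12	rs7046685	KIAA0101	chr9	28659143	chr15	64657210	64673702	-0.873	5.0499e-07	0.095
M12	rs12341535	KIAA0101	chr9	28663042	chr15	64657210	64673702	-0.873	5.0499e-07	0.095
M12	rs17101861	KIAA0101	chr14	34232772	chr15	64657210	64673702	-0.873	5.0499e-07	0.095
M12	rs6756606	CDK1	chr2	178700057	chr10	62538211	62554610	-0.688	5.2009e-07	0.095
M12	rs10497482	CDK1	chr2	178805428	chr10	62538211	62554610	-0.688	5.2009e-07	0.095
M12	rs6756606	KIAA0101	chr2	178700057	chr15	64657210	64673702	-0.955	5.5269e-07	0.095
M12	rs10497482	KIAA0101	chr2	178805428	chr15	64657210	64673702	-0.955	5.5269e-07	0.095
M12	rs2714384	BIRC5	chr18	25302948	chr17	76210276	76221716	-0.348	6.4318e-07	0.098
M12	rs2617950	BIRC5	chr18	25309414	chr17	76210276	76221716	-0.348	6.4318e-07	0.098
M12	rs2851757	BIRC5	chr18	25313101	chr17	76210276	76221716	-0.348	6.4318e-07	0.098
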