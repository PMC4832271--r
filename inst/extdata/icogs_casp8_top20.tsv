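snp_id	or	ci_low	ci_high	maf	p_rank	bf	bf_rank	delta_r2	rank_r2	delta_r5	rank_r5	group
838	1.041	1.020	1.062	0.338	5	330	5	0.346	3	0.693	1	4
837	1.042	1.021	1.064	0.299	6	306	10	0.329	4	0.677	2	4
1027	1.046	1.024	1.068	0.285	2	955	2	0.433	2	0.565	3	3
980	1.048	1.027	1.071	0.294	1	1932	1	0.436	1	0.345	4	2
896	1.042	1.020	1.064	0.287	13	254	12	0.169	5	0.257	5	3
885	1.041	1.019	1.063	0.287	19	184	16	0.129	7	0.201	6	3
893	1.080	1.032	1.131	0.047	42	30	45	0.046	25	0.170	7	4
839	1.035	1.013	1.057	0.270	54	26	50	0.040	29	0.151	8	4
992	1.045	1.022	1.067	0.287	3	488	3	0.163	6	0.117	9	2
909	1.043	1.021	1.065	0.287	9	352	4	0.124	8	0.087	10	2
950	1.043	1.021	1.065	0.286	10	326	6	0.115	9	0.081	11	2
960	1.043	1.021	1.065	0.285	7	320	7	0.114	10	0.080	12	2
961	1.043	1.021	1.065	0.285	8	320	7	0.114	10	0.080	12	2
985	1.043	1.021	1.066	0.286	4	310	9	0.111	12	0.078	14	2
907	1.042	1.020	1.064	0.287	6	255	11	0.093	13	0.065	15	2
912	1.042	1.020	1.064	0.287	15	254	12	0.092	14	0.065	16	2
890	1.028	1.008	1.048	0.386	141	9	149	0.014	45	0.057	17	4
956	1.052	1.025	1.080	0.167	16	210	14	0.078	15	0.054	18	2
1272	1.075	1.036	1.116	0.071	14	190	15	0.071	16	0.049	19	2
971	1.083	1.034	1.135	0.049	31	40	34	0.028	30	0.048	20	3
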