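section	level	cases_n	cases_pct	noncases_n	noncases_pct
age_category	<50	22	5.7	1095	10.8
age_category	50-54	68	17.7	2418	23.7
age_category	55-59	78	20.3	2107	20.7
age_category	>=60	217	56.3	4571	44.8
smoking_status	never	50	13.0	2933	28.8
smoking_status	ex	179	46.5	4358	42.8
smoking_status	current	156	40.5	2900	28.4
pack_years_current	<10	22	14.1	494	17.1
pack_years_current	10-19	24	15.4	343	11.8
pack_years_current	>=20	110	70.5	2063	71.1
bp_category	<140/90	113	29.4	3552	34.8
bp_category	140/90-159/99	161	41.8	3847	37.8
bp_category	>=160/100	111	28.8	2792	27.4
antihypertensive_use	yes	79	20.5	2079	20.4
antihypertensive_use	no	306	79.5	8112	79.6
bmi_category	<18.5	0	0.0	56	0.6
bmi_category	18.5-24.9	127	33.0	3794	37.2
bmi_category	25-29.9	195	50.6	5030	49.4
bmi_category	>=30	63	16.4	1301	12.8
followup_years	<5	52	13.5	448	4.4
followup_years	5-9	68	17.7	735	7.2
followup_years	10-14	80	20.8	1076	10.6
followup_years	>=15	185	48.0	7932	77.8
education	elementary	179	46.6	4665	45.9
education	lower_secondary	76	19.8	1992	19.6
education	upper_secondary	43	11.2	1215	12.0
education	post_secondary	32	8.3	945	9.2
education	university	54	14.1	1351	13.3
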