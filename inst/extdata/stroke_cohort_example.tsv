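id	sex	age	side	location	lesion_volume	wcst_ll	months_post	nihss	chedoke_arm	chedoke_hand	chedoke_leg	chedoke_foot
S1	M	63	L	subcortical	3548	868	3	1	6	6	6	5
S2	M	66	R	subcortical	541	268	10	1	6	6	5	5
S3	F	57	R	cortical-central	54452	209	3	1	6	6	6	7
S4	F	67	R	posterior-limb-internal-capsule	325	265	6	2	7	7	6	NA
S5	M	60	L	basal-ganglia	43391	550	20	4	5	3	6	5
S6	M	69	L	basal-ganglia	135833	350	23	6	3	2	6	4
S7	M	61	R	cortical-MCA	342741	92	6	6	2	2	5	3
S8	M	57	R	subcortical-MCA	282043	611	72	7	2	2	5	2
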