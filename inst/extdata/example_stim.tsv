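subject_id	x_mm	y_mm	z_mm	positive_motor	negative_motor	sensory	speech	silent
S01	7.35153704350814	15.4317832896765	-0.589712681472301	0	0	0	1	0
S01	13.3035788766202	2.75144621444866	11.1956062859483	0	1	0	0	1
S01	14.7105576416105	15.1418234964274	0.448868840709327	0	0	1	0	0
S01	-13.9837871821225	8.57337072861381	0.975512062003837	1	1	0	0	0
S01	8.34315388396382	7.02729961775243	2.1985960826464	0	0	0	0	0
S01	-7.01061966237612	16.2690371908341	-8.55203474471346	0	0	0	0	0
S01	-13.1022466333117	0.205434497762472	12.383146801265	0	0	0	0	0
S01	14.8752930708323	-0.329459516303615	5.06214128052816	0	0	0	0	1
S01	-2.76471079749986	4.88652643561363	-0.577529491754248	0	0	0	0	0
S01	-1.47084479883313	10.8372180659138	15.4309361531027	0	0	0	0	0
S02	-1.30955117133446	13.1423853986152	-10.5914227120019	0	0	0	0	0
S02	3.9985705146566	12.8291916169412	-10.68675233013	0	0	0	0	0
S02	-3.65542518485337	7.31776280522346	12.859798591258	0	0	1	0	0
S02	-16.1640222700126	2.12317197346129	7.97162387651391	0	0	0	0	0
S02	14.3593332986813	-3.64913646024652	1.99783203707076	1	0	0	0	1
S02	-8.44647501217201	8.05662914207205	-14.0463797232416	0	0	0	0	1
S02	2.14887680931017	12.9539914477989	11.5834365197271	0	0	0	0	0
S02	-10.4537453800812	10.1253543284442	13.5531712082773	1	0	0	1	0
S02	13.2513967418857	10.4355776441004	-8.99716699484736	1	0	0	0	0
S02	-13.6186168429535	-2.5814890302904	4.21162995857187	0	0	0	0	0
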