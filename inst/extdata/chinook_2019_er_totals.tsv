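population	cwt_catch	cwt_escapement	er_cwt	gsi_catch	gsi_escapement	er_gsi
Kitsumkalum	152.6	749.7	16.9	1891	6673	22.1
Atnarko	746.1	1342.6	35.7	6482	11675	35.7
Phillips	119.5	1191.1	9.1	326	2531	11.4
Shuswap	454.5	5160.2	8.1	4165	45187	8.4
Nicola	29.4	1199.6	2.4	45	3858	1.2
Harrison	293.2	1895.0	13.4	4735	47532	9.1
Chilliwack	1277.4	9027.2	12.4	6699	74037	8.3
Quinsam	1079.9	1712.2	38.6	3460	6784	34.2
Puntledge fall	70.0	226.3	23.6	7340	17045	30.1
Big Qualicum	206.9	387.0	34.8	6432	9681	39.9
Cowichan	621.5	591.9	51.2	9541	18109	34.5
Robertson	9775.6	3764.3	72.2	95067	37568	71.7
Bedwell	158.4	90	63.7	404	399	55.3
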