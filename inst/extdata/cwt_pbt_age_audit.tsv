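population	cwt_age	class	pbt_age	n
Quinsam	3	two_parent	3	26
Quinsam	4	two_parent	3	2
Quinsam	4	two_parent	4	319
Quinsam	4	one_parent	4	44
Puntledge summer	2	two_parent	2	1
Puntledge summer	3	two_parent	3	29
Puntledge summer	3	one_parent	3	1
Puntledge summer	4	two_parent	4	10
Puntledge fall	2	two_parent	2	7
Puntledge fall	3	two_parent	3	70
Puntledge fall	3	two_parent	4	2
Puntledge fall	3	one_parent	3	19
Puntledge fall	4	two_parent	4	16
Puntledge fall	4	one_parent	4	4
Qualicum	2	two_parent	2	14
Qualicum	2	one_parent	2	4
Qualicum	3	two_parent	3	72
Qualicum	3	one_parent	3	10
Qualicum	4	two_parent	4	18
Qualicum	4	one_parent	4	5
Robertson	2	two_parent	2	2
Robertson	3	two_parent	3	73
Robertson	3	one_parent	3	8
Robertson	4	two_parent	4	13
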