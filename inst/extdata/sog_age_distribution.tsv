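region	size_class	age	n
north	legal	2	3
north	legal	3	511
north	legal	4	101
north	legal	5	2
north	sublegal	2	67
north	sublegal	3	33
south	legal	2	3
south	legal	3	180
south	legal	4	40
south	sublegal	2	80
south	sublegal	3	36
south	sublegal	4	1
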