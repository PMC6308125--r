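subset	node
DMN	0
DMN	3
DMN	9
DMN	17
DMN	22
DMN	28
DMN	35
DMN	41
FPN	5
FPN	12
FPN	19
FPN	26
FPN	33
FPN	47
FPN	55
EN	7
EN	14
EN	21
EN	38
EN	44
EN	52
EN	60
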