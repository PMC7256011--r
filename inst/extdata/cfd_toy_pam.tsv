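pam	penalty
AGG	1
CGG	1
GGG	1
TGG	1
AAG	0.25
CAG	0.25
GAG	0.25
TAG	0.25
AGA	0.2
CGA	0.2
GGA	0.2
TGA	0.2
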