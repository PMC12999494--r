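category	grade	n
negative	all	120
positive	all	353
hi	G1	22
hi	G2	139
hi	G3	58
hi	undefined	4
low	G1	46
low	G2	84
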