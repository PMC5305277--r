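table	category	match	mismatch
impact	HIGH	280	2
impact	MODERATE	7254	112
impact	LOW	2651	45
impact	MODIFIER	46	34
effect	missense	7238	134
effect	nonsense	255	5
effect	synonymous	2738	54
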