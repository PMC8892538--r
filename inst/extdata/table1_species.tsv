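species	family	diploid_2n
puma	felidae	38
cheetah	felidae	38
leopard	felidae	38
tiger	felidae	38
clouded_leopard	felidae	38
dingo	canidae	78
african_wild_dog	canidae	78
red_fox	canidae	34
black_bear	ursidae	74
grizzly_bear	ursidae	74
polar_bear	ursidae	74
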