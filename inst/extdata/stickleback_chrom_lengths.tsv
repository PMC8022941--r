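chrom	v4_reference	paxton_assembly
chrI	29714595	30291332
chrII	23752435	24322974
chrIII	17815537	17075251
chrIV	34244925	35558100
chrV	15579443	16703751
chrVI	18862055	18511259
chrVII	30864241	33510017
chrVIII	20606801	22749572
chrIX	20880404	21858600
chrX	18035923	17341068
chrXI	17683359	18065382
chrXII	20811783	20111693
chrXIII	20800062	22032464
chrXIV	16179395	15892220
chrXV	17375354	18397630
chrXVI	19558478	18726499
chrXVII	20254007	21751973
chrXVIII	15989023	15795861
chrXX	20484364	21645813
chrXXI	17480265	17105228
chrXIX	20618466	20783580
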