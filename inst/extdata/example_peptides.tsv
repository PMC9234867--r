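sequence	form	evidence	t_cell	references
LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF	native	immunogenic	CD4	alpha2-gliadin 33-mer
LGQQQPFPPQQPY	native	toxic	none	gliadin p31-43 region 13-mer
QLIPCMDVVL	native	immunogenic	CD8	alpha-gliadin p123-p132
LQLQPFPQPELPYPQPQLPYPQPQLPYPQPQPF	deamidated	immunogenic	CD4	alpha2-gliadin 33-mer (predicted deamidated)
LQLQPFPQPQLPYPQPELPYPQPQLPYPQPQPF	deamidated	immunogenic	CD4	alpha2-gliadin 33-mer (predicted deamidated)
LQLQPFPQPQLPYPQPQLPYPQPELPYPQPQPF	deamidated	immunogenic	CD4	alpha2-gliadin 33-mer (predicted deamidated)
LQLQPFPQPELPYPQPELPYPQPQLPYPQPQPF	deamidated	immunogenic	CD4	alpha2-gliadin 33-mer (predicted deamidated)
LQLQPFPQPELPYPQPQLPYPQPELPYPQPQPF	deamidated	immunogenic	CD4	alpha2-gliadin 33-mer (predicted deamidated)
LQLQPFPQPQLPYPQPELPYPQPELPYPQPQPF	deamidated	immunogenic	CD4	alpha2-gliadin 33-mer (predicted deamidated)
LQLQPFPQPELPYPQPELPYPQPELPYPQPQPF	deamidated	immunogenic	CD4	alpha2-gliadin 33-mer (predicted deamidated)
LGQEQPFPPQQPY	deamidated	toxic	none	gliadin p31-43 region 13-mer (predicted deamidated)
LGQQQPFPPEQPY	deamidated	toxic	none	gliadin p31-43 region 13-mer (predicted deamidated)
LGQEQPFPPEQPY	deamidated	toxic	none	gliadin p31-43 region 13-mer (predicted deamidated)
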