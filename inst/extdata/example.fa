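>hairpin9 synthetic triple-stem example
GGGAAACCC
>mixed19 synthetic mixed example
GGGAAACCCAUGCUAGCUA
>random76 synthetic uniform-random 76-mer (random_sequence seed 42)
AAAACUCCAUGUGUAACUCCGGAAGUAGAAUCUUGCACUCGGCCUUUCCAUAUCUCGUGAACCCCCUGCACGCCCU
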