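>hdac5 orientation=sense span=1169-1188 reference=AF207748
aggctgagaggcaggccctt
>miD2861 orientation=antisense span=1169-1188 reference=AF207748
aagggcctgcctctcagcct
>USP1 orientation=sense span=971-980 reference=AF207748
acggctttactggctcagtc
>hdac5AS2 orientation=antisense span=2341-2360 reference=AF207748
atctcattccacaccgtgtc
>USP2 orientation=sense span=1781-1800 reference=AF207748
tcaaggatgaggatggcgag
>passenger orientation=sense
cuccggcucccccuggccucccgg
>premiR2861 orientation=sense
gaacuacaagucccagggggccuggcggcgggcggag
>mpremiR2861a orientation=antisense
ccctgggacttgtagttc
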