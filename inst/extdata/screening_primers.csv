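# Screening primers for exconjugant genomic DNA (published primer table).
gene,primer,sequence
mad10,fwd,CCTTCAAGAGATCCCCGAGG
mad10,rev,CGTCATCGGAACTCCCTGG
mad31,fwd,CTCCTTCTGTTTGGGTGACG
mad31,rev,GAGTGCTTCAGGTGAGAACG
tmn8,fwd,GGTCTCAGCCCGTCGTTC
tmn8,rev,TGTGCTGCTCGACCTGTC
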