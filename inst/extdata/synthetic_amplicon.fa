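>synthetic_45SM_promoter_amplicon synthetic 317 bp fixture (not a genomic sequence)
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCG
GGGTTCCACCCCAGGTCGGTCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTC
CTGGTGACCAGGCGCATCTATGGTATCTAGCCGAACCCTTAAACAGCGGCGGTAATCTCA
CGGGGGTATGATGTCTATGATCACCCGACGGGGCGAGTTACTCTCGTAATAGGAATCCTC
TTGCATGTACAGGAAGTGATTAAAATAATCCCATAACCCTCCACTCCTCTAATTGTTACT
AAGAGACCCTGAGAAAG
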