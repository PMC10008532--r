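>synthetic_ref_1 Imtechella halotolerans (synthetic random stand-in, not the public accession)
CCCTCGGATTCCAGACGGCAGATAAACGACTGGAACCTTTCGGGGGAAGAGTACTTCCCTGTGACCGGTTTAAGTCTTTGCCTAATTTAGCCAAGGACAATCGGTGCGCACTTTCTGATGGACCTCCGGCTCCTAACACTAGAATAAGTATGCGCTCCACACCTGAAGGGACGCGGGTACTACTGTACTTTCTTCTAGGGTGTTTTCGGTCCGGCTGAAGTATGGCTCGCGACGTGGATCTAAAGACAAT
>synthetic_ref_2 Allobacillus halotolerans (synthetic random stand-in, not the public accession)
AGACCGATCTTTAAGGTGCTTCCGTTAGCCTAGTAGGGGCTGGTGAAGGGTCCGGCGCGCTGGCTATGATCAGCAAACTTTTCACTGTACAGTGCTAGTGTTAAATGCATCGTGAATAATTTCGGTAGCACCTCCAGTCCTGTACACAACACCAGGACTCTCACGCGAGGCTTGAAGACCGTCCAGCGATTTGAACCCAGATATAAGTCACTCATTCTAATGAGGCCGAGATCGCCATAGTGAGTGTCAA
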