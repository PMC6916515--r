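>synthetic_smlp1 synthetic stand-in cDNA for the HrSMLP1 self-marker (2344 bp)
CCTCAGTTAGGCTCGTTATCTAGGTCACACAATTAGTTGGCGGGATCGCCTACACTAGTAGTGCGTTACT
ACTTTTACAAAAAACGATCCTACTTCTCTTTCAACCTTCTGTTGACCCCGATGCGTATGGTCCGTGTCGG
AGTCGCTATCATCGAAGGACTGCACATCATGGGAGTCGTCATGATCGTCTTCAAAGGACAATGGGGAATG
GCTCGTCAAGGACAAGACCACGGAAAACGTGCTGCTCGTTTCCAAAAAGCTGAAGACCGTCAAGGACTGG
GAATCCAAGCTATGATCGACAACGGAAGCATGCTGGAAGAAGCTGTCTGGCTGAAAGAAGGAGTCGTCCA
AGTCGTCTTCCAAGCTGAAGAACGTCGTGGATGGCGTGTCGCTGTCGTCGTCCGTCAAAAACTGGAACGT
GGAGAATGGGCTATCCACGGAGACTGGTACAAAGACTGGGCTAAATGCTGGCGTTACGGATTCATCAAAC
TGGCTCGTTTCGACAAAGGACTGGAAATGCAAATGGTCGTCTGGGCTGTCGTCCAAGACATCATCCGTTA
CGCTGGAGAACTGGACGTCCACCAAATCGTCAAACAAGGATGGATCCACCTGCGTGGAGGAGACGTCATG
ATGAAACAAGGATTCCAAGCTCAAGGAGGAGCTATCATGATCCAAGGACTGATCGCTGTCGGAGTCGCTG
TCATGCTGCAACACCTGAACGGAAGCGCTAAACTGGCTTTCGGAGGAGCTGGAGGAGCTCTGGTCGAAGC
TCTGATCCAACTGCAACTGGCTTGGTACCTGCAAATGATCGCTCAATTCGTCGGACTGGAATTCCAAGTC
GCTGACGGACGTGAATTCGCTGAACAAGCTTGCGCTCTGGTCTTCATGTGGTGGTTCGTCATCCAATACA
TCCGTGCTGGACAACACGGACTGGCTGCTGAAAAAGCTTGCCTGGTCGGAAAAGTCGGAGGAAAAGCTGA
CGTCGAACTGCAACAAGCTTACGCTGGAGTCGCTCAAATCATCAAAGGAGGACTGCACCGTGAAGGATAC
CAAAAAGAAGCTATCCGTGTCGACCACGCTTGGGACATCGCTGCTGAAGACTGGTGGCAAAAACGTCTGG
GAGTCATCCTGAAAAACGGAAGCTTCCGTTTCGAAGGAATCGCTATCTGCCACGCTGAACGTCAAGTCAT
CGCTGTCGCTAAAGCTGGAGGATTCGCTGCTTGGATCCTGTGGAAATACAAAGTCGCTGCTAAACTGGGA
CAACACTGGTGGTTCATCGCTGCTGCTGACCAAGAATTCGCTGCTGGAGCTCAAATCCTGCAAGACTTCT
TCATGGGAGCTTGGGGAATGGTCGGAGGACTGGTCGCTGAAATCGGATTCGGAGGATGGGCTGTCGCTGG
AGAAATGCTGGCTCAAGGACAATTCATCATCGGACTGGGAGAAGCTATCTTCGGAATGGGAGGAATGGGA
GAATTCTGGCTGCTGAAAGTCTACGGAGCTCAAATCCGTATCTTCTGCGTCGGAGAAGGAGCTGTCGAAG
AAGTCGCTGTCAACGGAAGCGGAGGATTCATCTGGGAAGCTGTCCTGGACGGACAAGGAGAAGTCTTCAT
CATGGGAGTCATGATGATGATCGGAATCCGTCGTTTCCTGTACGACTACGTCTGGGCTGGACTGGAAGTC
TTCGTCATCGTCGCTTGGGACTGGGTCAAAGCTCTGGAACAAGACCTGGACGTCGGAGTCATGCACGCTC
TGGTCGGAATCTGGCAATGGTTCGTCGGACAAAAACTGCTGGGAGAACAAGCTGACAAACGTTGGGTCCA
AGCTATCATGTGGGCTGACCTGTTCATGGTCCAATTCAAACTGTGCGCTGTCGACGCTGAAGAATACGCT
ATCCTGATCGACGCTAAAATGGTCGGAGAATGGTGGCTGGGAGCTATCCAAGTCGTCGACATCCACGGAG
CTCTGGGAAACGGAAGCATCGACAAAGGAGGATTCGGAGTCTGGATGGTCCAACTGCACGTCTGGCACCA
ACGTTTCGTCTTCATCATCCAAATCGCTGACGACATGTTCGCTCACCGTGGAGGAATCGCTGTCGGAATC
TGGGGACAAGACTAAAGAAGGTAGTGGGCTATACAGATCAAACGTTCGACCTGATCTAGTTCTCTAATTA
CTTGAGTGTCTCGGGGCTGCTGCGAACTTACCCTTCCATCATTCCGTTCTGCAAGCAGGCTGTCCCGTTG
ATCTCCATTCCCTCGTCTCCACTCGCTCCTGTGTCAGGCCTTCTGCCCCTCCCTTACAAGGAGTCGCCTC
TTATAGAACCCTACGTCTACTTGGGTTCAAAGTG
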