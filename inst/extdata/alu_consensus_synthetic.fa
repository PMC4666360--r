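>AluY synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGATACAACAAAACACGATATAAATGTGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTTACATACGGTTAACACTGCGGCTATTATGCCTAAGCG
TGAGGATACCAATTGTCACCAAGCAGTGATGCGGCTGTGCTAATATAAGACCAATTAGTA
TATACGGAATGGGTTTTACCGCTGGTGATATGCTGCAATGTATTCCTCCCCGCCTCTGCG
AAGCTGTCTCTGGTCATTGCCCTCAAACAGCCTCCCAAAGT
>AluYa5 synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGATACAACAAAACACGATATAAATGTGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTTACATACGGTTAACACTGCGGCTATTATGCCTAAGCG
TGAGGATACCAATTGTCACCGAGCAGTGATGCGGCTGTGCTAATATAAGACCAGTTAGGA
TATACGGAATGGGTTTTACCGCTGGTGATATGCTGCAATGTATTCCGCCCCGCCTCTGCG
AAGCTGTCTCTGGTCATTGCCCTCTAACAGCCTCCCAAAGT
>AluYa8 synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGAACCGGATACAACAAAACACGATATAAATGTGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTTACATACGGTTAACACTGCGGCTATTATGCCTAAGCG
TGAGGATACCAATTGTCACCGAGCAGTGATGCGGCTGTGCTAATATAAGACAAGTTAGGA
TATACGGAATGGGTTTTACCGCTGGTGATCTGCTGCAATGTATTCCGCCCCGCCTCTGCG
AAGCTGTCTCTGGTCATTGCCCTCTAACAGCCTCCCAAAGT
>AluYb8 synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGATACAACAAAACACGATATAAATGCGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTTACATACGGTTAACACTGCGGCTATTATGCCTAAGAG
TGAGGATACCAATTGTCACCAAGCAGTGATGTGGCTGTGCTAATATAAGACCAATTAGTA
TATACGGAATGGGTTTTGCCGCTGGTGATATGCTGCAATGTATTCCTCCCCGCCACTGCG
AAAATGTCTCCGGTACCTGGTCATTGCCCTCAAACCGCCTCCCAAAGT
>AluYb9 synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGATACAACAAAACACGATATAAATGCGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTTACTTACGGTTAACACTGCGGCTATTATGCCTAAGAG
TGAGGATACCAATTGTCACCAAGCAGTGATGTGGCTGTGCTAATATAAGACCAATTAGTA
TATACGGAATGGGTTTTGCCGCTGGTGATATGCTGCAATGTATTCCTCCCCGCCACTGCG
AAAATGTCTCCGGTACCTGGTCATTGCCCTCAAACCGCCTCCCAAAGT
>AluYc1 synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGATACAACAAAACACGATATAAATGTGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTTACATACGGTTAACACTGCGGCTATTATGCCTAAGCG
TGAGGATACCAATTGTCACCAAGCAGTGATGCGGCTGTGCTAATATAAGACCAATTAGTA
TATACGGAATGGGTTTGACCGCTGGTGATATGCTGCAATGTATTCCTCCCCGCCTCTGCG
AAGCTGTCTCTGGTCATTGCCCTCAAACAGCCTCCCAAAGT
>AluYd8 synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCCGATACAACAAAACACGATATAAATGTGTACGCGTAAGA
GATGCCGCATCGGTAATGGGATTTACATAGGGTTAACACTGCGGCTATTATCCCTAAGCG
TGAGGATACCAAATGTCACCAAGCAGTGATGCGGCTGTGCTAATATAAGACCAATTAGTA
TATAGGGAATGGGTTCTACCGCTGGTGATATGCTGCAATGTATTCCTCCCCGCCTCTGCG
AAGCTGTCTCTGGTCATTGCCCTCAAACAGCCTCCCAAAGT
>AluYe5 synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGATATAACAAAACACGATATAAATGTGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTTACATACGGTTAACACTGCGGCTATTATGCCGAAGCG
TGAGGATACGAATTGTCACCAAGCAGTGATGCGGCTGTGCTAATATAAGACCAATTAGTA
TATACGGAATGGGTTTTACCGCTGGCGATATGCTGCAATGTATTCCTCCTCGCCTCTGCG
AAGCTGTCTCTGGTCATTGCCCTCAAACAGCCTCCCAAAGT
>AluYg6 synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGCTACAACAAAACACGATATAAATGTGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTTACATACAGTTAACACTGCGGCTATTATGCCTAAGCG
TGAGGATACCGATTGTCACCAAGCAGTGATGCGGCTGTGCTAATATAAGACCAATTAGTA
TTTACGGAATGGGTGTTACCGCTGGTGATATGCTGCAATGTATTCCTCCCCGCCTCTCCG
AAGCTGTCTCTGGTCATTGCCCTCAAACAGCCTCCCAAAGT
>AluSx synthetic consensus (not RepBase)
GGCCGGGCGCGGGTCCGCACCGGATACAAGAAAACACGATACAAATGTCTACGCGGAAGG
GATGTCGCATATGTAATGTGATTTACATACGGTTCACACTGCGGCTATTATGCCTAAGCG
TGAGGATACCAATTGTCACCAAGCAGTGATGAGGCTGTGCTAACATAAGACCAATTAGTA
TATACGGAATGGGTTTTAGCGCTGGTGATATGCTGCAATGTATTCCTCCCCGCCTCTGCG
AAGCTGTCTCTGGTCATCGCCCTCAAACAGCCTCCCAAAGT
>AluSp synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGATAAAACAAAACACGATATAAATGTGTACGCGTAAGA
GATGCCGCATCTGTAATGTGATTGATATACGGTTAACACAGCGGCTATTATGCCTAAGCG
TGACGATACCAATTGTCACCAAGCAGTGCTGCGGATGTGCTAATATAAGACCAGTTAGCA
TCTACGGAATGGGGCTTACCGCTGGTGATACGCTGTAATGTACTCCTCCCCGCCTCTGCG
AAGCTGTCTCTGGTCATTGCCCTCAAAAAGCCTCCCAAAGT
>AluJb synthetic consensus (not RepBase)
GGCCGGGCGCGGGTACGGACCGGATACAACAAAACACGATATAAAGGTTTCCGCGTCAGA
GATGCCGCATCGGCAATGTGATTTACATACGGTTAAAACTGCGGATATTATGCCTAAGCG
TGAGTATACGAATTGTCACCAAGCAGTGATGAGGCCGTGCTAATGTAAGACCAAGTAGTA
TATACGGAGTGGGTTGTACCGCTGGTGATATGCTGCAATGTATTGTTCCCCGCGTCTGCG
AATCTGGCTCTGGTCGTTGCCTTCAAAAAGCCTCCCAAAGT
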