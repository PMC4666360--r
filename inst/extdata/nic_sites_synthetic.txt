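TTAAC
TTAAA
TGTCG
TTAAG
TAAAC
CTAAC
TTAAA
TTAAA
TTCGA
TTAAA
ACTAA
TTAAA
TTAAA
TTAGA
TTAGT
TTGGC
TTAAG
TGACA
GTTAA
TTCAA
TTACA
TTAAT
CTAAA
TTAAA
TAAAA
TTAAC
TGAAT
TTATA
TTATT
TCAAA
CTAAA
TTAAC
TTAAT
TCAAT
TTACG
TTAGA
TTAAT
TTAGC
TTCAG
TTAGC
TTAAA
TTAGC
TTAAA
TTTAG
TTAAG
TTAAA
TTAAA
TTAAA
ATAAT
TTAAA
TTTAG
TTATG
TTGAC
TTAAT
GGCAG
AAACG
TTAAA
TCAAA
TTAAA
TTAAA
TATAG
TTAGA
TTTAC
TTAAT
TTAAG
TTAAT
TTGAG
TTACA
TTAAC
TTTAA
TTTCA
TTATA
TCTAA
TACAA
ATGAA
TTAAC
TTAAA
GTGAA
TTAAC
TTAAC
TATAA
TTAAA
TTTAG
CTCAA
TTCAA
TTAAT
ATAAA
TACTC
TTGAT
TTCAG
TTAAA
TTAAA
TTATA
GCAAC
TTAGA
TTACC
TAAAA
TTAAT
TTAGA
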