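>holotype_COI_barcode 657 bp
AACATTATATTTTATTTTTGGTATTTGAGCAGGAATAGTAGGAACATCTCTAAGAATTTT
AATTCGTATGGAATTAAGAACTCCTGGATCCTTAATTGGAAATGATCAAATTTATAATAC
TATTGTTACAGCTCATGCATTTATTATAATTTTTTTTATGGTTATACCTATTATAATTGG
AGGATTTGGTAACTGATTAGTTCCCTTAATATTAGGAGCACCTGATATAGCCTTTCCCCG
ATTAAATAATATGAGATTTTGATTATTACCACCATCATTAATACTACTAATTTCTAGAAG
AATTGTAGAAAATGGTGCAGGAACAGGATGAACAGTTTACCCCCCACTTTCATCAAATAT
TGCACATAGAGGATCATCTGTAGATTTAGCAATTTTCTCTCTTCATTTAGCAGGAATTTC
TTCAATTTTAGGAGCAATTAATTTTATTACAACTATCATTAATATACGAGTAAATAATTT
ATCTTTTGATCAAATATCATTATTTATTTGAGCAGTGGGAATTACAGCATTATTATTACT
TTTATCATTGCCTGTATTAGCTGGAGCAATTACCATATTACTAACAGATCGAAACCTTAA
TACCTCATTCTTTGACCCAGCTGGTGGAGGAGATCCAATTTTATATCAACATTTATT
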