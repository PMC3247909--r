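>snow_leopard_synthetic
CGATGATTCGTAGAGGCCGTCTTGGTGGTTGCCTAGAGAGTCTCGGTAACTCGTTTCTAT
CACTGGATGGTCGATGGGGGTCTCTACCAGCAGTTAGCAAATGGTTTTTTACATACAACA
TCGTACGGTCTCTGCCTGAACTGCCGCCCAGGGTGGACTGTCCACTGCCTAAAGAATCAC
CCGCGAAACTCCAAGTCTTTCGAATTCACGGAAACACGAGCTTACCGCAAGGATTGGGCA

>tiger_synthetic
CGATGATTCGTAGAGGCCGTCTAGGTGGTTGCCTAGAGAGTCTCGGTAACTCGTTTATTT
CACTGGATGGTATATGGGGGTTGGTACCAGCAGTTAGCAAATGGTTTTTAACATACAACA
TCGTACGGGCTCTGCCTGAACTGCCGCCCAGGGGGGACAGTCGACTGCCTAAAGGATCAC
CCTAGAAACTCATATTCTGTCCCATTAAAGGATACACGAGCTTACCGCAAGGATTGGGCA

>leopard_synthetic
CGATGATTCGTAGAGGCCGGCTTGGTGGTTGCCAAGAGAGTCTCTGTAACCCGTTTATTT
CAATGAATAGCCGATGGCAGTCTCTACCAGGAGTTAGCAAATGGTTTTTTTCATACAACA
TCGTACGGTCTCTGCCTGAACTGATGCCCAGCGTGGACTGTCCACTGCCTAAAGAATCAC
CCGCGAAACTCAAATTCCGTTGCATTAAAGGAAACACGAGCTGACCGCAAGGATTGGGCA

>lynx_synthetic
CGATGATACATAGAGGCCGTCTTAGTGGTTGTCTAGAGAGTCTCGGTAACTCGTTTATTT
CACTTGATGGTCGATGGGGGTCTTTACCAGCAGTTAGCAAATGGTTTTTTACATACAATA
TCGTACGGTCCCGGCTTGAACTACCGCCCACGGTGGTCTGGCCAAGGCCTAAAGAATCAC
CCGCGAAACTCAAATTCTGTCGCATTAAAGGAAACAGGAGCTTACCGCAAGGATTGGGCA

>wolf_synthetic
CCATGATTCGTAGTTGCCGTCTTGGTGGTTGCCTAGAGAGACTCGGTAACTCGTGTAATA
CAGTGGATGGTCGATGGGGGTCTCTACCAGCAGCTAGCAAATGGTTTTTTACATACAACA
TCGTACGGTCTCTGCCTGAACTGCGGCCCAGGGTGGACGGTACACTGCCTTAAGAATCAC
CCGCGAAACTCAAATTCAGTAGCATTAGAGGAAACACGAATTTACCGCAAGGATTGGGCA

>red_fox_synthetic
AGATGATTCGTAGAGGCCGTCTTGGAGGTTGCCCAGAGAGTCTCGGTAACTCGGTTATTT
CACTGGTTGGTCGATGGGGGTCTCTACCAACAGTTAGCAAATGGTTTATTACATACAACA
TCGTACGGTATCTGTCTGCACTGCCACCCAGGGTGGACTGACCACTGCCTAAAGAATCAC
CCGCGAAACTCAAATTCTGTCCCATTAAAAGAAACACTAGCTTACAGCAAGGATTCGACA

>sheep_synthetic
CGATGAATCGGAGAGGCCGTCTTGGGGGTCGCCTAGAGAGTCTCGGTTACTCGTTTAATT
CACTGAATGGTCGATGGGGGTCTCGGCCAACAGTTAGCAAATGGTTTTTGACATACAACA
TCGTACGGTCTCTGCCTGAACTGCCGCCCAGGGTGGACTGGCCACTGCCTAAAGAATCAC
CCGCGAAACTCAAATTCTGCCGCTTTAAAGCAAACACGAGCTTACCACAAGGATTTGGCA

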