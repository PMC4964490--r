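>signal_long21 synthetic family consensus, 21-aa signal peptide
MAKRLVLFAAVVIALVALTTA
>signal_short18 synthetic consensus, 18-aa signal peptide (hexapeptide-deleted lineage)
MAKRLVLFAAVVIALVAL
>n_terminal_105 extra_q=54 synthetic consensus, 105-aa N-terminal, 5 Cys, ends SSQTVQ
EGEASEQLQCERELQELQERELKACQQVMDQQLRDISPECHPVVVSPVAGQYEQQVVVPPCGGSFYPGETTPPQQLQQRIFWGIPALCKRGQYYPTSVTSSQTVQ
>n_terminal_102 extra_q=51 synthetic consensus, 102-aa N-terminal (hexapeptide-deleted lineage), ends SSQPVQ
ASEQLQCERELQELQERELKACQQVMDQQLRDISPECHPVVVSPVAGQYEQQVVVPPCGGSFYPGETTPPQQLQQRIFWGIPALCKRGQYYPTSVTSSQPVQ
>c_terminal_42 synthetic consensus, 42-aa C-terminal containing LAAQLPAMCRL, 1 Cys
YHVSVSAEYQAARLKVAKAQQLAAQLPAMCRLEGGDALSASQ
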