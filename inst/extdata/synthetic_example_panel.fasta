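>ced_rep_01 synthetic representative CeD protein
CGFGSKFRKYRARGGLAPGFPQQPFPQQPGQPDPQQTQQPFYQQPQQPFPQQPQQPFPQQ
PQQPFPQQPQQPFPHQPQQPFPQQPQQPFPEQPGQPFVQQPFQPFPQQPQQPFPQQPQQP
FPQQPQQPFPQQPQQPFLGQQQPFPPQQPYQPFPQQPQQPFPQQPQQPFPLQLQPFPQPQ
LPYPQPQLPYPQPQLPYPQPQPFQPQQPFPQQPQQPFPQQPVQPFPQQPQQPFPQQPQQP
FPQQPQQPFPQQPQQPFPQQPQQHFPQGPQQPFPQQPQQPFPQQQLIPCMDVVLQPFPQQ
AKILTKNQGKPRYKLITYSH
>ced_rep_02 synthetic representative CeD protein
DPGTIQRRNLNIEARQSLFDPQQPFPQQPQQPFPQQPQQPFHQQPQQPFPPQQPDPQQPQ
QPFPQPQQPQQPFPQQPQQPFPQQPQRPFPQQPQQPFPQQPQQPFPQQPQQPFPQQPQQP
FPQQPQQPFPQQDQQPFWQQPQQPFPQQPQQPFPQQPQQIFPQQDQQPFPQQPQQPFPQQ
PQQPFNQQPQQPFPQQPQQPFWQQPQVPFPQQPQQPFPQQPPQQSFPQQPQQPPQQPQQP
FPQQPQQPFPQQNRGKNRPQQPFPEQPKALRK
>ced_rep_03 synthetic representative CeD protein
SMSGSESEQTLKKSMKDKKDPQQPFTWLPQQPFWQQPQQPFPQQPQQPFPQQPQQPFPQQ
PQQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQPTQPFPQQPQQPFPQQPQQPFPQIPQQP
FPQQPQQHFPQQPQQPFPQQPQQPFNQQPQQPQQPDPQQPQQPFPQQPFPQQPQQPFPQH
PQQPFPEAPQQHFPQQPAQPFPQQNQQPFPQQPQQPFPQQPPQQPFNQQPQQFPQQPQQP
FPQQPQQPFPQQYQQPFPQQPQQPFPQMSQVQTLSCVGTEQNMVIYLI
>ced_rep_04 synthetic representative CeD protein
ADTNKGIADKAHVLAGLDSPPQQPFPQQPQQPFPQQPPQQPFNQQPQQFPQQPQQPFPQQ
PWPQQTFPQQPQDPLQPQQPFPQQPQQPFPQQPQQPFPQQPQQPFNQTPQQPFPQQPQQP
FPQQPQQPFPQQPQQPFPQQPQQPFDQQPQQPFPQQPQQPPQQSFPQQPQQPPQQPFPQQ
PQQPFPQQPQQPFPQQPQFPFPQQPHQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQAVLQ
SVYIIVSLDPSNLKRI
>ced_rep_05 synthetic representative CeD protein
HVSPQVPQQPFNQQPQQCDKPQQPFPQQPQQPFPQQPQQPQQPFPEQPFPYQPQMPFPQQ
PQIPFPQQPQQPFPQQPQQPFPQQPQQCFPQQPDQPFPQQPQQPFPQQPQQPFPQQPQQP
FPQQPQQPFPQKPHQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQ
PQQYFPQQGQQPFPQQSQQPFPQQPQQPFPQQHFPQQPQQPQQPFPQQPQQPFGQQPQQP
FPQQPQQPFPQQPQQPFPQQPQQPFPQQAKLIELEEIVYESLLFFADP
>ced_rep_06 synthetic representative CeD protein
ASEDSVPQQTFPQQPQDEEQPSQPFPQMPQQPFPQQPQQPFPPQQPFNQQPQQQQPRPQQ
PQQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQPQQPFQQQPCQPFPQQPQQPFPQFPQQP
FFQQPQQPFPQYGQQPFPQQPQQPFPQQPQQPFPQQPQQPFPKQPQQPFPQQAQQPFPQQ
PQQPFPQNPQQCFPQQPQQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQPQQPFPQQPQQP
FPQYPQGPFPQQPQQPFPQQPQQPFPQQPQPQQPFPEQPSFPMQMKLGGDSVRAYWNDFI
AITI
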