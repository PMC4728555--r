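>sgRNA_scaffold_px330 chimeric crRNA-tracrRNA scaffold (SpCas9, pX330-style)
GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGT
GGCACCGAGTCGGTGC
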