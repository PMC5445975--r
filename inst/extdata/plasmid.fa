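>demo_plasmid synthetic stand-in (not the real Cas9/sgRNA vector), circular, insertion point 20
ATCGGTACCTAGGCATCGATTTGACGCATGCAAGCTTGCACCGGATATCGGCCTAGCTAG
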