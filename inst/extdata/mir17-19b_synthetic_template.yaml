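name: mir17-19b
n_hairpins: 4
segments:
- fixed: TGCTGTCAGTGAGCG
- slot: sense_1
- fixed: GTGAAGTCACAATCAA
- slot: antisense_1
- fixed: CACCGGTCTCGGA
- slot: sense_2
- fixed: GTATTAGTTATCTCCA
- slot: antisense_2
- fixed: CTTGGCATTCCGG
- slot: sense_3
- fixed: GTGATAGTCAAATCGT
- slot: antisense_3
- fixed: CAGGTACCTTGAA
- slot: sense_4
- fixed: GTACCTGCTGAACTGA
- slot: antisense_4
- fixed: TGCCTACTGCACTCGGA
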