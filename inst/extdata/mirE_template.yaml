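name: mirE
n_hairpins: 1
segments:
- fixed: TGCTGTTGACAGTGAGCG
- slot: sense_1
- fixed: TAGTGAAGCCACAGATGTA
- slot: antisense_1
- fixed: TGCCTACTGCCTCGGA
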