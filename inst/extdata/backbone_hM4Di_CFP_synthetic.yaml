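# Synthetic stand-in backbone: layout (hSyn promoter, reporter ORF,
# 3'-UTR insertion point) mirrors the real lentiviral vector, but the
# sequences are short placeholders, not the real plasmid.
promoter_name: hSyn
promoter_seq: CACCACCTCCACCTCACCAACC
orf_name: hM4Di_CFP
orf_seq: ATGCACCAACAAACCCACCCAAACACCACCCTAA
utr3_remainder: CCTCCACCAACCTCACCAACCACC
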