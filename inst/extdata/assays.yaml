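# Two-gene CNV sexing assay for Leptinotarsa decemlineata:
# X-linked voltage-sensitive sodium channel gene (target) quantified against
# the autosomal ubiquitin-protein ligase E3B gene (reference).
# Coordinates are 1-based inclusive positions on the named scaffold.
assays:
  - gene_name: LdVssc
    role: target
    scaffold_accession: NW_019291534.1
    forward_primer_seq: AGAATCATGGATTGTCCGAAGGTT
    reverse_primer_seq: GAGGGTGGTAAGAGTGGCAAAAGT
    forward_span: [14058, 14081]
    reverse_span: [14277, 14300]
    expected_amplicon_bp: 243
  - gene_name: LdUBE3B
    role: reference
    scaffold_accession: NW_019289582.1
    forward_primer_seq: AACAACTGCAGCATCTGAAACTCC
    reverse_primer_seq: TACGGCTTTGAACACTTTGACACA
    forward_span: [72367, 72390]
    reverse_span: [72593, 72616]
    expected_amplicon_bp: 250
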