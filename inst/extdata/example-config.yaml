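# Desk-scale pipeline configuration: two sex-linked region classes, a
# genomic-only cross and a shortened X-like chromosome.
regions:
  Xpr:
    n_genes: 8
    dS_XY: 0.063
    dS_X_OG: 0.120
    omega_X: 0.315
    omega_Y: 0.591
    y_expression: 0.6
  qXdr:
    n_genes: 8
    dS_XY: 0.091
    dS_X_OG: 0.123
    omega_X: 0.267
    omega_Y: 0.408
    y_expression: 0.2
n_codons: 80
cross:
  n_sons_rna: 0
  n_daughters_rna: 0
map:
  chrom_length: 1.0e8
  distal_p_length: 1.0e7
  distal_q_length: 6.0e6
  n_markers: 150
expression:
  n_males: 8
  n_females: 8
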