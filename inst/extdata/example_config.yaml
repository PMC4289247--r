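# Example run configuration. Values marked genome_default_* are the defaults
# used for the genome-scale worm/fly-style analysis; scale them down for
# desk-size experiments.
inputs:
  species:
    worm:
      expression: expr_worm.tsv        # genes x stages TSV
    fly:
      expression: expr_fly.tsv
  orthologs: orthologs.tsv             # species_a  gene_a  species_b  gene_b
coexpression:
  d: auto          # genome_default_d: 5 (smallest d forming a giant component)
  d_max: 30
  log2: false
  signed: false
cost:
  kappa: 3         # genome_default_kappa: 3
  lambda: 1        # genome_default_lambda: 1
  signed: false
  normalize_layers: false
  weight_scheme: mean_recip
annealing:
  q: 250           # genome_default_q: 250
  R: 32            # genome_default_R: 32
  cooling: 0.9     # genome_default_cooling: 0.9
  stop_fliprate: 0.01
  sweeps: 20
  seed: 1
consensus:
  threshold: 0.95  # genome_default_threshold: 0.95
  min_size: 5      # genome_default_min_size: 5
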