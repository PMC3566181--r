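random_seed: 42
gc_window_bp: 1000
indel_slop_bp: 10
chrom_classes:
  chr1: autosome
pipeline:
  genome_length: 200000
  gc_target: 0.45
  gc_sd: 0.1
  snp_rate: 0.001
  indel_rate: 0.0002
  fragment_length: 100
  uniqueome_divergence: 0
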