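# Demonstration run: serial-founder expansion on an 8 x 8 deme grid seeded
# from its north-eastern corner, followed by the full spatial
# population-genomics analysis. All inputs are simulated; outputs are
# written to the directory passed to run_pipeline().
seed: 42
sim:
  grid_width: 8
  grid_height: 8
  deme_size: 100
  founders: 5
  migration: 0.01
  colonization_interval: 20
  post_expansion: 300
  burn_in: 10
  ancestral_Ne: 10000
  sample_per_deme: 2
ibd:
  n_perm: 9999
krige:
  family: exponential
  statistics: [heterozygosity, roh_count]
gradient:
  statistics: [heterozygosity, roh_count, ratio_ns, freq_ratio, lof_dosage]
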