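# Demo pipeline configuration: two synthetic streamlined genomes and one
# simulated intermediate-salinity community read set. Runs in well under a
# minute on one CPU. `out_dir` is usually overridden on the command line:
#   Rscript -e 'streamscan::run_pipeline(system.file("extdata/demo_config.yaml",
#     package = "streamscan"), out_dir = "demo_out")'
seed: 99
out_dir: demo_out
genomes:
  - id: sim1
    synthetic: {length: 60000, gc: 0.62, mean_gene_len: 900, mean_spacer: 15, seed: 101}
  - id: sim2
    synthetic: {length: 60000, gc: 0.55, mean_gene_len: 900, mean_spacer: 30, seed: 102}
reads:
  - id: meta
    simulate:
      n_reads: 4000
      read_length: 100
      error_rate: 0.005
      seed: 103
      members:
        - {genome: sim1, abundance: 0.8}
        - {genome: sim2, abundance: 0.2}
thresholds:
  spacer_policy: clamp
  recruit: {mode: abs_len, min_identity: 95, min_len: 50}
  ani: {fragment_len: 1020, min_identity: 30, min_cov: 0.7, k: 11}
  islands: {window: 10000, step: 1000, ratio_threshold: 0.2, merge_gap: 2000, min_len: 5000}
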