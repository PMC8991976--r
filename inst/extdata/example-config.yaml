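# Example gsbench experiment configuration (synthetic data).
# Causal SNP ids must exist in the simulated map: ids are
# "<chrom>_<9-digit position>"; run `simulate` once and pick ids from the
# emitted VCF, or keep this demo config as is (ids below match the map
# simulated from seed 42).
sim:
  n_lines: 200
  missing_rate: 0.002
  maf_range: [0.05, 0.5]
map:
  n_chrom: 2
  snps_per_chrom: 100
  chrom_length_bp: 4000000
traits:
  - name: flower
    kind: monogenic-categorical
    causal:
      - snp: PLACEHOLDER_CHR01      # replace with a SNP id from the map
        penetrance:                 # rows: REF_HOM, HET, ALT_HOM
          - [1.0, 0.0]
          - [0.0, 1.0]
          - [0.0, 1.0]
  - name: oil
    kind: polygenic-continuous
    heritability: 0.6
    causal:
      - { snp: PLACEHOLDER_CHR02A, effect: 1.0 }
      - { snp: PLACEHOLDER_CHR02B, effect: 0.7 }
options:
  cv_k: 5
  include_dl: false
  seed: 42
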