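{
  "chrom": "chr20",
  "start": 380879,
  "end": 380977,
  "ref_copies": 3,
  "unit_fasta": "demo_locus_unit.fa",
  "left_flank_fasta": "demo_locus_left_flank.fa",
  "right_flank_fasta": "demo_locus_right_flank.fa"
}
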