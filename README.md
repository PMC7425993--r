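# vntrkit

Genotyping of a promoter VNTR (variable number tandem repeat) copy number
from short sequencing reads, with population-genetic summaries and
copy-number-to-expression association analysis.

## The problem

A VNTR is a tandemly repeated motif (unit ≥ 7 bp) whose copy number varies
between alleles. The locus this package models is a promoter repeat with a
33-bp unit (reference: 3 copies, a 99-bp array), each copy carrying a
C/EBP-ATF response element (`TT(G/A)CATCA`), so copy number directly scales
regulatory input. Short reads cannot be reliably aligned through tandem
repeats, so `vntrkit` works alignment-free, for anyone who needs to
genotype such a locus in WGS cohorts and relate it to expression:

* **k-mer ratio estimator** of the diploid-average copy number
  `(c1 + c2)/2` from raw reads:

  ```
  CN = median(repeat 25-mer counts) /
       max(median(29 5'-flank 25-mer counts), median(29 3'-flank 25-mer counts))
  ```

  (`build_panel()`, `count_kmers()`, `estimate_cn()`, `estimate_cohort()`).

* **Spanning-read allele caller** for discrete genotypes: a read matching
  `6 bp left flank + c units + 6 bp right flank` within edit distance 2
  supports allele `c` (possible up to `C_max = floor((150 - 12)/33) = 4` at
  150 bp); reads carrying 4 full units plus a ≥ 6 bp repeat fragment that is
  not flank are the open class "5" (`call_reads()`, `genotype_sample()`).
  Alleles with < 2 supporting reads are dropped; samples with > 2 alleles
  are excluded. `scan_six_plus()` hunts for hypothetical ≥ 6-copy alleles.

* **Population genetics**: allele frequencies and the multi-allelic fixation
  index `F_ST = (H_T − H_S)/H_T` with `H = 1 − Σ p²`
  (`allele_frequencies()`, `pairwise_fst()`, `fst_matrix()`).

* **Association**: transcriptome-wide Pearson correlation of copy number
  with `log2(x + 1)` expression under Benjamini–Hochberg FDR, per-tissue
  screens (≥ 5 samples rule), SNP allele-effect OLS regression, composite
  LD r² (`correlate_cn_expression()`, `tissue_screen()`, `dosage_effect()`,
  `ld_r2()`).

* **Synthetic cohorts** (Hardy–Weinberg genotypes at the published allele
  frequencies 5x:0.42, 3x:0.34, 2x:0.23, 1x/4x rare; uniform-coverage reads
  with substitution errors; LD-controlled SNPs; expression matrices with one
  causal gene) so every stage is testable without controlled data
  (`sample_cohort()`, `simulate_reads()`, `simulate_linked_snp()`,
  `simulate_expression()`).

## Worked example

```r
library(vntrkit)

locus  <- synthetic_locus(seed = 101, flank_len = 600)   # demo locus
panel  <- build_panel(locus)                             # 10 repeat + 2x29 flank 25-mers
cohort <- sample_cohort(default_allele_freqs(), n = 30, seed = 7)
cfg    <- read_sim_config(read_length = 150, coverage = 30,
                          error_rate = 0.001, seed = 7, flank_len = 600)
sim    <- simulate_cohort_reads(cohort, locus, cfg)

kt <- estimate_cohort(sim$reads, panel)      # k-mer route
gt <- genotype_cohort(sim$reads, locus, span_config())  # spanning-read route
head(kt, 3); head(gt[, 1:6], 3); allele_frequencies(gt)
```

Output (abridged):

```
    sample median_repeat median_flank5 median_flank3 cn_estimate
4  ind0004         283.5            47            57    4.973684
30 ind0030         298.0            60            46    4.966667
12 ind0012         288.0            58            59    4.881356

   sample status allele1 allele2 reads1 reads2
1 ind0001 called       2       3     14     12
2 ind0002 called       5      NA     20     NA
3 ind0003 called       5      NA     15     NA

<allele_freq_table> 1 population(s)
  all (n=30): 1:0.017 2:0.283 3:0.250 5:0.450
```

Reading this: `cn_estimate` is the diploid-average copy number (ind0004 is
a 5/5 homozygote, truth 5.0, estimated 4.97 from the repeat-median 283.5
over the larger flank median 57). The spanning route calls ind0001 a 2/3
heterozygote from 14 and 12 supporting reads; ind0002 shows only the
open-class allele 5 (flagged single-allele, treated as 5/5 for
frequencies). The two routes agree at r = 0.949 on this cohort. An
end-to-end run (`run_pipeline()`) chains simulation → both genotypers →
frequencies → expression correlation and writes TSVs plus a config echo;
the `inst/cli/vntr-tools` script exposes each stage as a subcommand
(`kmer-genotype`, `span-genotype`, `fst`, `correlate`, ...).

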