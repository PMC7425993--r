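---
title: "Genotyping a promoter VNTR from short reads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping a promoter VNTR from short reads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrkit)
```

## The problem

A variable number tandem repeat (VNTR) is a stretch of DNA in which a motif
of at least 7 bp is repeated head to tail a variable number of times between
alleles. The locus modeled here is a promoter VNTR with a 33-bp unit and
three copies in the reference genome; each unit carries a C/EBP-ATF response
element (CARE, consensus `TT(G/A)CATCA`), so the allele's copy number sets
the number of regulatory elements and is functionally relevant. Short-read
sequencing makes such loci awkward: a 100-bp read cannot even span a 3-copy
array, and alignment through tandem repeats is unreliable. `vntrkit`
implements two complementary, alignment-free ways of reading copy number out
of raw reads, plus the population-genetic and expression-association
summaries built on top of them, and a synthetic-data generator that makes
the whole chain testable without access to controlled cohort data.

## The k-mer ratio estimator

For a diploid sample the quantity of interest is the *diploid-average* copy
number $(c_1 + c_2)/2$. Every 25-mer that lies inside the repeat unit occurs
once per repeat copy, while a 25-mer from the flanking sequence occurs once
per chromosome. With uniform coverage, the ratio of their sequencing depths
therefore estimates the diploid-average copy number:

$$\widehat{CN} \;=\; \frac{\mathrm{median}(\text{repeat 25-mer counts})}
{\max\left(\mathrm{median}(\text{5' flank counts}),\;
\mathrm{median}(\text{3' flank counts})\right)}$$

The panel (`build_panel()`) takes all step-1 25-mers: 9 fit inside a 33-bp
unit, and the default 10-k-mer repeat list is completed with a k-mer
spanning the unit-to-unit junction; junction k-mers occur $c-1$ times per
allele instead of $c$, which leaves the *median* over the list untouched for
every copy number (for $c = 1$ the junction k-mer simply drops to the bottom
of the list), but the per-k-mer diagnostics expose the difference. A
9-k-mer panel (`n_repeat = 9`) is the strictly unbiased choice. Each flank
contributes the 29 k-mers of its terminal 53-bp window. Counting
(`count_kmers()`) is canonical — every window is mapped to the
lexicographic minimum of itself and its reverse complement — because WGS
reads are unstranded; the reference k-mer tool's orientation handling is not
documented, but canonical counting is the only correct choice for raw
reads. Panel k-mers that also occur in the other region, or across an
array/flank boundary (where their multiplicity bookkeeping would be wrong),
are screened out up front; the builder warns when this happens.

Medians use the midpoint rule for even-length lists. When both flank
medians are zero the estimator raises an "insufficient flank coverage"
error rather than returning 0 or infinity.

## The spanning-read allele caller

Discrete alleles come from reads that traverse the whole array
(`call_reads()`, `genotype_sample()`). For each candidate copy number $c$ up
to $C_{max} = \lfloor (L - 2a)/U \rfloor$ (with read length $L = 150$,
anchor $a = 6$ and unit $U = 33$: $C_{max} = 4$), the expected sequence is
six left-flank bases, $c$ units, six right-flank bases; a read matching one
such pattern within edit distance 2 (semi-global alignment, both
orientations) supports allele $c$. Alleles beyond $C_{max}$ cannot be
spanned, so a read carrying $C_{max}$ full units plus an adjacent repeat
fragment of at least 6 bp — where that fragment is *not* explainable as
flank sequence within the same tolerance — supports the open class
$C_{max}+1$ (label 5 at 150 bp). The flank guard is not optional: without
it, every full-span read of a 4-copy allele would also count as evidence
for 5 or more copies. Per sample, alleles supported by fewer than 2 reads
are dropped; samples with more than two surviving alleles are excluded; a
single surviving allele is reported as a flagged single-allele call and
treated as homozygous by the frequency code.

`scan_six_plus()` searches for reads carrying 4 consecutive full units with
repeat-consistent partials at *both* ends, neither explainable as flank. A
partial at only one end is already explained by a 5-copy allele, so the
both-ends reading is the one that makes the scan specific; sliding a 150-bp
window over a 5-copy array can never place repeat partials on both sides of
four full units, which the test suite verifies exhaustively.

Edit distance is full Levenshtein (the standard meaning; whether the
original analysis allowed indels is not documented) with a substitution-only
Hamming mode available in `approx_contains()` for sensitivity analysis. The
matcher is implemented in C++ with a pigeonhole seed prefilter (one of
`max_edit + 1` pattern segments must occur exactly) and row-minimum early
abort, and the test suite checks it against a brute-force dynamic-programming
oracle.

## Population summaries

`allele_frequencies()` counts two gene copies per called sample.
`pairwise_fst()` implements the Nei-style multi-allelic fixation index on
mean frequencies, $F_{ST} = (H_T - H_S)/H_T$ with
$H = 1 - \sum_i p_i^2$; populations are weighted equally by default
(`weighting = "by_n"` switches to sample-size weights) and no small-sample
correction is applied unless `bias_correct = TRUE` (the source publication
cites its $F_{ST}$ definition from the literature without restating
weighting or bias handling, so both conventions are exposed and labeled).
$H_T = 0$ (both populations fixed for the same allele) yields an explicit
`undefined` flag.

## Association analyses

Expression values (TPM/FPKM-like) are log-transformed — base and offset are
not documented in the source analysis, so the default is $\log_2(x+1)$ and
both are configurable — and related to copy number by Pearson correlation
with two-sided p-values from the t approximation. FDR control is
Benjamini-Hochberg, with two separate families mirroring the original
analyses: one across genes (transcriptome-wide screen), one across tissues
(`tissue_screen()`, which enforces the at-least-5-samples inclusion rule).
Genes with fewer than 3 pairs or zero variance are flagged untestable and
excluded from the family. No outlier exclusion and no covariate adjustment
are applied anywhere. `dosage_effect()` is OLS of a response on SNP dosage
with a t-test on the slope; `ld_r2()` is composite LD (squared Pearson
correlation of unphased dosages), the appropriate choice when only
genotype dosages are available.

## The synthetic-data generator

The generator states one fixed world and the tests measure the methods in
it:

* **Allele frequencies** default to the published cohort values
  (`default_allele_freqs()`: 0.42 / 0.34 / 0.23 for 5x / 3x / 2x, 0.005 for
  the rare 1x and 4x), haplotypes drawn i.i.d. (Hardy-Weinberg).
* **Reads** (`simulate_reads()`): uniform start positions over each
  haplotype's allele sequence with configurable flank window (default 2 kb,
  standing in for a ±10 kb extraction; tests use 600 bp purely for speed —
  the 53-bp normalization windows sit hundreds of bases from any edge either
  way), per-base substitution errors, strand flipped with probability 0.5,
  constant placeholder qualities. Coverage is per haplotype; 30x is a
  conventional default, not a documented cohort property. No indels, PCR
  duplicates, GC bias or quality modeling — the callers tolerate edit
  distance 2 and substitutions exercise exactly that tolerance.
* **Linked SNPs** (`simulate_linked_snp()`): haplotype SNP alleles drawn
  conditionally on the VNTR allele from a joint frequency table, so LD is
  controlled exactly.
* **Expression** (`simulate_expression()`): gene 1 has
  $\log_2$ expression $= \beta \cdot \bar c + N(0, \sigma)$, all other genes
  are independent noise; `calibrate_effect()` pins $\beta$ to a target
  population correlation (0.42 reproduces the published blood value given
  the default frequencies). Baseline 5 on the log2 scale (~32 TPM-like
  units) keeps the $+1$ offset negligible.

Everything is bit-reproducible given a seed; per-sample substreams derive
from the global seed so extending a cohort never changes existing samples.

A green test in this world establishes that the *procedures* behave as
specified under idealized uniform coverage and substitution-only noise. It
does not establish performance on real WGS (alignment artifacts, coverage
waves, PCR stutter in the repeat, indel errors are all absent).

## Measured limitations (from the acceptance suite)

Three acceptance properties fail in the stated world, and the failures are
informative about the method rather than the code:

* **Denominator max-bias.** At 30x, a flank k-mer count has mean ~57 and SD
  ~7, and the 29 k-mers of a 53-bp window fluctuate almost in lockstep, so
  each flank median keeps nearly the full SD. Taking the *max* of two such
  medians (as the published formula prescribes) inflates the denominator by
  ~7% on average, biasing estimates down by about 0.3 at a diploid mean of
  5 — outside the ±0.2 recovery band the acceptance suite demands. The
  counting itself is exact (verified against a start-position oracle).
* **4-copy spanning window.** A 4-copy full span needs 144 of 150 bases, so
  only ~7 read start positions produce it; at 30x that is under 2 expected
  reads, and the ≥2-read filter then misses the allele ~30% of the time,
  turning 4-carrying heterozygotes into confident homozygous calls. Exact
  recovery of such genotypes at 30x/150 bp is statistically impossible; the
  published analyses also report 4x as a sub-1% allele detected across
  thousands of samples, consistent with per-sample sensitivity well below 1.
* **Concordance ceiling.** The same denominator noise gives per-sample
  estimator SD ~0.33 against a cohort truth SD of 0.89, capping the
  k-mer-vs-spanning correlation near 0.94 at n = 100 (the suite asks for
  0.95).

All other acceptance properties — frequency recovery within exact binomial
bands, closed-form and convergent $F_{ST}$, the end-to-end association
pipeline finding the causal gene in ≥90% of replicate cohorts with uniform
null p-values, the specificity/sensitivity of the ≥6-copy scan, and the
oracle equivalences — hold at their stated tolerances.

## Numerical and interface choices

* Coordinates in configs are 1-based inclusive; `coords_0based()` is the
  only converter to BED-style half-open.
* The repeat unit and flank sequences of the real locus are not printed in
  any public source bundled here; the package ships a clearly synthetic
  fixture locus (random sequence with the CARE motif at the documented unit
  position, fixed seed) and users supply real sequences via FASTA + JSON
  config.
* Ties and degenerate inputs: even-length medians use midpoints; ambiguous
  full-span matches (two patterns within tolerance, possible only through
  flank/unit sequence coincidence plus errors) are dropped with a warning
  rather than arbitrarily resolved; constant dosages and fixed-fixed
  population pairs return explicit errors/flags, never NaN.
* All pipeline outputs are plain TSV with a JSON config echo; identical
  config and seed give byte-identical outputs.
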