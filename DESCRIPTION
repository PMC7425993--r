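Package: vntrkit
Title: Genotyping of Promoter VNTR Copy Number from Short Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the copy number of a variable number tandem
    repeat (VNTR) from short-read sequencing data. Implements an alignment-free
    k-mer ratio estimator of the diploid-average repeat copy number, a
    spanning-read allele caller with approximate (edit distance bounded)
    pattern matching for discrete genotypes, population summaries (allele
    frequencies and pairwise multi-allelic fixation indices), and
    copy-number-to-expression association analysis (Pearson correlation with
    Benjamini-Hochberg false discovery rate control, per-tissue screens, SNP
    allele-effect regression, and composite linkage disequilibrium r-squared).
    A synthetic cohort generator (Hardy-Weinberg genotypes, uniform-coverage
    reads with substitution errors, haplotype-linked SNPs, and expression
    matrices with a configurable causal effect) makes every stage testable
    without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Rsamtools,
    GenomicRanges,
    IRanges,
    withr
Config/testthat/edition: 3
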