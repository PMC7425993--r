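# Shared fixtures: one synthetic locus (600-bp flanks keep simulations fast
# while leaving the 53-bp normalization windows deep in the interior) and
# small simulation wrappers. All seeds are fixed constants.

fixture_locus <- synthetic_locus(seed = 101, flank_len = 600)
# the fixture flank happens to extend the repeat by chance at one boundary,
# so the builder skips two contaminated junction k-mers (warning expected)
fixture_panel <- suppressWarnings(build_panel(fixture_locus))
fixture_span <- span_config()

sim_ind <- function(c1, c2, seed, coverage = 30, error_rate = 0,
                    read_length = 150, locus = fixture_locus) {
  cfg <- read_sim_config(read_length = read_length, coverage = coverage,
                         error_rate = error_rate, seed = seed, flank_len = 600)
  simulate_reads(list(id = sprintf("g%d_%d", c1, c2),
                      hap1_copies = c1, hap2_copies = c2), locus, cfg)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Independent brute-force semi-global edit distance (full DP, no shortcuts),
# minimum over both read orientations.
edit_oracle_one <- function(p, t) {
  pc <- strsplit(p, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(pc); n <- length(tc)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + (pc[i] != tc[j]),
                               D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  min(D[m + 1L, ])
}

revcomp_oracle <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

edit_oracle <- function(p, t) {
  min(edit_oracle_one(p, t), edit_oracle_one(p, revcomp_oracle(t)))
}

# Unordered diploid genotypes over alleles 1..5
all_genotypes <- function() {
  g <- expand.grid(c1 = 1:5, c2 = 1:5)
  g[g$c1 <= g$c2, ]
}

# A genotype call matches the truth when alleles <= 4 are recovered exactly
# and alleles >= 5 appear as the open-class label 5.
truth_labels <- function(c1, c2, open_label = 5L) {
  sort(pmin(c(c1, c2), open_label))
}

call_matches_truth <- function(geno_row, c1, c2, open_label = 5L) {
  if (geno_row$status != "called") return(FALSE)
  called <- if (is.na(geno_row$allele2)) rep(geno_row$allele1, 2L)
            else c(geno_row$allele1, geno_row$allele2)
  identical(sort(as.integer(called)), as.integer(truth_labels(c1, c2, open_label)))
}
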