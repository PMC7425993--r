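test_that("sample_cohort draws Hardy-Weinberg genotypes", {
  # degenerate distribution
  co <- sample_cohort(c(`3` = 1.0), 10, seed = 1)
  expect_true(all(co$hap1_copies == 3) && all(co$hap2_copies == 3))
  expect_true(all(co$diploid_mean == 3))

  # non-normalized frequencies
  expect_error(sample_cohort(c(`2` = 0.6, `3` = 0.5), 10, seed = 1), "sum to 1")
  expect_error(sample_cohort(c(0.5, 0.5), 10, seed = 1), "named")

  # heterozygote fraction under HWE: 2pq = 0.5, binomial SD at n = 10000
  co <- sample_cohort(c(`2` = 0.5, `5` = 0.5), 10000, seed = 42)
  het <- mean(co$hap1_copies != co$hap2_copies)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))

  # determinism
  expect_identical(sample_cohort(default_allele_freqs(), 50, seed = 9),
                   sample_cohort(default_allele_freqs(), 50, seed = 9))
})

test_that("empirical allele frequencies converge to the specified ones", {
  freqs <- default_allele_freqs()
  co <- sample_cohort(freqs, 10000, seed = 7)
  obs <- table(factor(c(co$hap1_copies, co$hap2_copies), levels = names(freqs)))
  chi <- suppressWarnings(stats::chisq.test(obs, p = freqs))
  expect_gt(chi$p.value, 0.001)
})

test_that("simulate_reads obeys the read-count, error and strand model", {
  loc <- fixture_locus
  ind <- list(id = "s1", hap1_copies = 3, hap2_copies = 3)

  # error-free reads are exact substrings of the haplotype sequence or its rc
  cfg <- read_sim_config(coverage = 5, error_rate = 0, seed = 3, flank_len = 600)
  sim <- simulate_reads(ind, loc, cfg)
  hap <- build_allele_sequence(loc, 3, 600, 600)$seq
  both <- paste(hap, revcomp_oracle(hap), sep = "NNN")
  expect_true(all(vapply(sim$reads, grepl, logical(1), x = both, fixed = TRUE)))

  # read count = 2 * round(coverage * L / read_length)
  L <- nchar(hap)
  expect_identical(length(sim$reads), 2L * as.integer(round(5 * L / 150)))

  # strand flips about half the time
  frac_minus <- mean(sim$truth$strand == "-")
  expect_lt(abs(frac_minus - 0.5), 0.1)

  # substitution rate recovers the configured error rate (3 SD binomial band)
  cfg2 <- read_sim_config(coverage = 30, error_rate = 0.01, seed = 4, flank_len = 600)
  sim2 <- simulate_reads(ind, loc, cfg2)
  n_mm <- 0L; n_tot <- 0L
  for (i in seq_along(sim2$reads)) {
    rd <- sim2$reads[[i]]
    if (sim2$truth$strand[i] == "-") rd <- revcomp_oracle(rd)
    src <- substr(hap, sim2$truth$start[i], sim2$truth$start[i] + 149L)
    n_mm <- n_mm + sum(strsplit(rd, "")[[1]] != strsplit(src, "")[[1]])
    n_tot <- n_tot + 150L
  }
  expect_lt(abs(n_mm / n_tot - 0.01), 3 * sqrt(0.01 * 0.99 / n_tot))

  # haplotype shorter than the read length is an error
  tiny <- vntr_locus("c", 1, 33, loc$unit_seq, "ACGTACGTAC", "ACGTACGTAC", 1)
  expect_error(
    simulate_reads(ind, tiny, read_sim_config(coverage = 5, seed = 1, flank_len = 10)),
    "shorter than read_length")
})

test_that("read truth tables round-trip through TSV", {
  co <- sample_cohort(default_allele_freqs(), 3, seed = 5)
  cfg <- read_sim_config(coverage = 3, seed = 6, flank_len = 600)
  sim <- simulate_cohort_reads(co, fixture_locus, cfg)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(sim$truth, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.table(tmp, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_identical(back$read_id, sim$truth$read_id)
  expect_identical(back$copies, sim$truth$copies)
  # every read's source haplotype and each individual's true diploid mean are
  # recoverable
  expect_true(all(back$hap %in% 1:2))
  dm <- tapply(back$copies, list(back$id, back$hap), unique)
  expect_equal(rowMeans(dm), stats::setNames(co$diploid_mean, co$id))
})

test_that("cohort read simulation is reproducible and stable under extension", {
  co <- sample_cohort(default_allele_freqs(), 4, seed = 8)
  cfg <- read_sim_config(coverage = 2, seed = 11, flank_len = 600)
  a <- simulate_cohort_reads(co, fixture_locus, cfg)
  b <- simulate_cohort_reads(co, fixture_locus, cfg)
  expect_identical(a, b)
  # adding individuals does not perturb existing substreams
  co6 <- sample_cohort(default_allele_freqs(), 6, seed = 8)
  co6[seq_len(4), ] <- co
  c6 <- simulate_cohort_reads(co6, fixture_locus, cfg)
  expect_identical(c6$reads[1:4], a$reads)
})

test_that("simulate_linked_snp produces the configured linkage", {
  co <- sample_cohort(c(`2` = 0.5, `5` = 0.5), 2000, seed = 13)
  # perfect coupling: VNTR 5 <-> SNP 1
  tab <- data.frame(vntr_allele = c(2, 5), snp_allele = c(0, 1),
                    freq = c(0.5, 0.5))
  snp <- simulate_linked_snp(co, tab, seed = 14)
  expect_gt(cor(snp$dosage, co$hap1_copies + co$hap2_copies)^2, 0.95)

  # independence table: slope of dosage on copy number ~ 0
  ind_tab <- expand.grid(vntr_allele = c(2, 5), snp_allele = c(0, 1))
  ind_tab$freq <- 0.5 * 0.5
  snp0 <- simulate_linked_snp(co, ind_tab, seed = 15)
  fit <- dosage_effect(co$diploid_mean, snp0$dosage)
  expect_lt(abs(fit$beta), 0.1)

  # malformed table
  bad <- data.frame(vntr_allele = c(2, 5), snp_allele = c(0, 1),
                    freq = c(0.4, 0.5))
  expect_error(simulate_linked_snp(co, bad, seed = 1), "sum to 1")
  # cohort allele missing from the table
  expect_error(
    simulate_linked_snp(sample_cohort(c(`3` = 1), 5, seed = 1), tab, seed = 1),
    "zero marginal")
})

test_that("simulate_expression couples only the causal gene to genotype", {
  co <- sample_cohort(default_allele_freqs(), 200, seed = 21)

  # strong effect, small noise: r > 0.9 between copy number and causal gene
  cfg <- expression_sim_config(n_genes = 5, beta = 1, sigma = 0.1, seed = 22)
  x <- simulate_expression(co, cfg)
  expect_true(all(x > 0))
  expect_gt(cor(co$diploid_mean, log2(x[, 1])), 0.9)

  # global null: ~5% of genes reach p < 0.05
  cfg0 <- expression_sim_config(n_genes = 1000, beta = 0, sigma = 1, seed = 23)
  x0 <- simulate_expression(co, cfg0)
  res <- correlate_cn_expression(stats::setNames(co$diploid_mean, co$id),
                                 log_transform(x0))
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  expect_error(expression_sim_config(n_genes = 0, beta = 1, sigma = 1), "n_genes")
  expect_error(expression_sim_config(n_genes = 5, beta = 1, sigma = 0), "sigma")
})

test_that("effect calibration hits a target population correlation", {
  freqs <- default_allele_freqs()
  beta <- calibrate_effect(0.42, sigma = 1, cn_var = cohort_cn_variance(freqs))
  co <- sample_cohort(freqs, 475, seed = 31)
  cfg <- expression_sim_config(n_genes = 1, beta = beta, sigma = 1, seed = 32)
  x <- simulate_expression(co, cfg)
  r <- cor(co$diploid_mean, log2(x[, 1]))
  expect_lt(abs(r - 0.42), 0.1)
})
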