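test_that("max_fully_spannable follows the floor formula", {
  cfg <- span_config()
  expect_identical(max_fully_spannable(150, fixture_locus, cfg), 4L)
  expect_identical(max_fully_spannable(100, fixture_locus, cfg), 2L)
  expect_identical(max_fully_spannable(300, fixture_locus, cfg), 8L)
  expect_error(max_fully_spannable(10, fixture_locus, cfg), "exceed")
})

test_that("approx_contains agrees with direct construction", {
  set.seed(501)
  read <- rand_dna(150)
  pat <- substr(read, 40, 80)
  expect_identical(approx_contains(read, pat, 2), 0L)

  # one substitution inside the pattern region
  mut <- paste0(substr(read, 1, 59), "N", substr(read, 61, 150))
  mut <- chartr("N", setdiff(c("A", "C", "G", "T"), substr(read, 60, 60))[1], mut)
  expect_identical(approx_contains(mut, pat, 2), 1L)

  # reverse complement of the read matches equally
  expect_identical(approx_contains(revcomp_oracle(read), pat, 2), 0L)

  # three substitutions exceed the tolerance
  pat3 <- pat
  for (i in c(5, 15, 25)) {
    b <- substr(pat3, i, i)
    substr(pat3, i, i) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  expect_identical(edit_oracle(pat3, read), 3L)
  expect_true(is.na(approx_contains(read, pat3, 2)))

  # hamming mode is at least as strict as levenshtein
  expect_identical(approx_contains(read, pat, 2, mode = "hamming"), 0L)
  expect_error(approx_contains(read, "", 2), "non-empty")
})

test_that("call_reads classifies constructed spanning reads", {
  loc <- fixture_locus
  cfg <- fixture_span
  u <- loc$unit_seq
  lf <- loc$left_flank_seq; rf <- loc$right_flank_seq

  embed <- function(core, left = 20, right = 20) {
    paste0(substr(lf, 600 - left + 1, 600), core, substr(rf, 1, right))
  }
  # exact full span of 2 copies embedded in extra flank sequence
  r2 <- embed(strrep(u, 2))
  expect_identical(call_reads(r2, loc, cfg), 2L)
  expect_identical(call_read(r2, loc, cfg)$allele, 2L)

  # full spans for each c in 1..4
  for (c in 1:4) {
    expect_identical(call_reads(embed(strrep(u, c), 6, 6), loc, cfg), c)
  }

  # a 150-bp read drawn inside a 5-copy array: 4 full units + 18 nt partial
  arr5 <- strrep(u, 5)
  inside <- substr(arr5, 16, 165)
  expect_identical(nchar(inside), 150L)
  expect_identical(call_reads(inside, loc, cfg), 5L)

  # 3 full units, no flank anchors, < 6 nt beyond: no evidence
  frag <- substr(strrep(u, 4), 30, 30 + 99 + 4)   # 3 units + 4 nt partials
  expect_true(is.na(call_reads(frag, loc, cfg)))

  # strand symmetry
  expect_identical(call_reads(revcomp_oracle(r2), loc, cfg), 2L)
  expect_identical(call_reads(revcomp_oracle(inside), loc, cfg), 5L)

  # none of this yields ambiguous double matches
  expect_silent(call_reads(c(r2, inside, frag), loc, cfg))
})

test_that("partial evidence is rejected when explainable as flank", {
  loc <- fixture_locus
  cfg <- fixture_span
  u <- loc$unit_seq
  # 4 units followed by right flank: full-span fails (no left anchor) and the
  # right-side fragment is flank, so no open-class call either
  rd <- paste0(strrep(u, 4), substr(loc$right_flank_seq, 1, 18))
  expect_true(is.na(call_reads(rd, loc, cfg)))
  # same read with a repeat fragment instead is open-class evidence
  rd2 <- paste0(strrep(u, 4), substr(u, 1, 18))
  expect_identical(call_reads(rd2, loc, cfg), 5L)
})

test_that("genotype_sample applies the count and allele filters", {
  loc <- fixture_locus
  cfg <- fixture_span
  u <- loc$unit_seq
  span_read <- function(c) {
    paste0(substr(loc$left_flank_seq, 581, 600), strrep(u, c),
           substr(loc$right_flank_seq, 1, 20))
  }
  # evidence {2:5, 3:7, 4:1}: the count-1 allele is excluded -> {2,3}
  reads <- c(rep(span_read(2), 5), rep(span_read(3), 7), span_read(4))
  g <- genotype_sample(reads, loc, cfg, sample_id = "a")
  expect_identical(g$status, "called")
  expect_identical(g$alleles, c(2L, 3L))
  expect_identical(g$counts, c(5L, 7L))
  expect_false(g$single_allele)

  # evidence {2:3, 3:3, 5:2}: three surviving alleles -> excluded
  arr5_read <- substr(strrep(u, 5), 16, 165)
  reads3 <- c(rep(span_read(2), 3), rep(span_read(3), 3), rep(arr5_read, 2))
  g3 <- genotype_sample(reads3, loc, cfg)
  expect_identical(g3$status, "excluded_multiallelic")

  # no evidence at all
  set.seed(502)
  g0 <- genotype_sample(vapply(1:5, function(i) rand_dna(150), ""), loc, cfg)
  expect_identical(g0$status, "no_call")
  expect_identical(g0$alleles, integer(0))

  # single surviving allele: called, flagged
  g1 <- genotype_sample(rep(span_read(3), 4), loc, cfg)
  expect_identical(g1$status, "called")
  expect_true(g1$single_allele)
  expect_identical(g1$alleles, 3L)
})

test_that("genotype_cohort tabulates statuses and evidence", {
  reads_23 <- sim_ind(2, 3, seed = 503)$reads
  reads_55 <- sim_ind(5, 5, seed = 504)$reads
  tab <- genotype_cohort(list(a = reads_23, b = reads_55), fixture_locus, fixture_span)
  expect_identical(tab$status, c("called", "called"))
  expect_identical(c(tab$allele1[1], tab$allele2[1]), c(2L, 3L))
  expect_identical(tab$allele1[2], 5L)
  expect_true(all(grepl("^\\{", tab$evidence_json)))
})

test_that("reverse-complementing every read leaves genotypes unchanged", {
  sim <- sim_ind(3, 5, seed = 505, error_rate = 0.005)
  g_fwd <- genotype_sample(sim$reads, fixture_locus, fixture_span)
  g_rev <- genotype_sample(vapply(sim$reads, revcomp_oracle, ""), fixture_locus,
                           fixture_span)
  expect_identical(g_fwd$alleles, g_rev$alleles)
  expect_identical(g_fwd$evidence, g_rev$evidence)
})

test_that("scan_six_plus flags interior reads of >=6-copy arrays only", {
  loc <- fixture_locus
  cfg <- fixture_span
  u <- loc$unit_seq

  # constructed 150-nt read: 9 nt unit suffix + 4 units + 9 nt unit prefix
  rd <- paste0(substr(u, 25, 33), strrep(u, 4), substr(u, 1, 9))
  expect_identical(nchar(rd), 150L)
  expect_identical(scan_six_plus(c(x = rd), loc, cfg), "x")

  # exhaustive slide of a 150-nt window over the full 5-copy allele: never
  # flagged (a 5-copy array cannot put repeat partials on both sides of 4
  # full units without hitting flank)
  hap5 <- build_allele_sequence(loc, 5, 300, 300)$seq
  starts <- seq_len(nchar(hap5) - 149L)
  wins <- substring(hap5, starts, starts + 149L)
  expect_identical(scan_six_plus(wins, loc, cfg), character(0))

  # a read from the 3-copy reference is not flagged
  ref_read <- substr(build_allele_sequence(loc, 3, 100, 100)$seq, 80, 229)
  expect_identical(scan_six_plus(ref_read, loc, cfg), character(0))

  # interior windows of a 6-copy array: flagged exactly when the combined
  # pattern (6-nt unit suffix + 4 units + 6-nt unit prefix) fits within the
  # edit tolerance; expectation computed with the independent DP oracle
  arr6 <- strrep(u, 6)
  s6 <- seq_len(198 - 149L)
  wins6 <- substring(arr6, s6, s6 + 149L)
  names(wins6) <- as.character(s6)
  pb <- paste0(substr(u, 28, 33), strrep(u, 4), substr(u, 1, 6))
  expected <- s6[vapply(wins6, function(w) edit_oracle(pb, w) <= 2L, logical(1))]
  flagged <- scan_six_plus(wins6, loc, cfg)
  expect_gt(length(flagged), 0L)
  expect_identical(as.integer(flagged), as.integer(expected))

  # configuration error when reads cannot hold 4 units + 2 fragments
  expect_error(scan_six_plus("ACGT", loc, span_config(read_length = 100)),
               "too short")
})
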