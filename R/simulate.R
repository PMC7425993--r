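#' Default VNTR allele frequencies for simulation
#'
#' Allele frequencies of the 33-bp promoter repeat observed in a large
#' European cohort: the 5-copy allele is most common (0.42), followed by the
#' 3-copy (0.34) and 2-copy (0.23) alleles, with 1- and 4-copy alleles rare
#' (below 1%).
#'
#' @return Named numeric vector (names = copy numbers) summing to 1.
#' @export
default_allele_freqs <- function() {
  c(`1` = 0.005, `2` = 0.23, `3` = 0.34, `4` = 0.005, `5` = 0.42)
}

check_freqs <- function(freqs, tol = 1e-9) {
  if (is.null(names(freqs)) || anyNA(suppressWarnings(as.integer(names(freqs))))) {
    stop("freqs must be a named vector with integer copy-number names")
  }
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > tol) {
    stop("frequencies must sum to 1 (got ", format(sum(freqs), digits = 12), ")")
  }
  invisible(freqs)
}

#' Sample a diploid cohort under Hardy-Weinberg equilibrium
#'
#' Haplotype copy numbers are drawn i.i.d. from `freqs`, so genotype
#' proportions follow Hardy-Weinberg expectations.
#'
#' @param freqs Named numeric vector of allele (copy number) frequencies;
#'   must sum to 1 within 1e-9.
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed; the cohort is fully determined by
#'   `(freqs, n, seed)`.
#' @return A `data.frame` of class `vntr_cohort` with columns `id`,
#'   `hap1_copies`, `hap2_copies`, `diploid_mean`.
#' @examples
#' head(sample_cohort(default_allele_freqs(), 5, seed = 1))
#' @export
sample_cohort <- function(freqs, n, seed) {
  check_freqs(freqs)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  alleles <- as.integer(names(freqs))
  if (any(alleles < 1L)) stop("haplotype copy numbers must be >= 1")
  with_seed(seed, {
    h1 <- alleles[sample.int(length(alleles), n, replace = TRUE, prob = freqs)]
    h2 <- alleles[sample.int(length(alleles), n, replace = TRUE, prob = freqs)]
    out <- data.frame(
      id = sprintf("ind%04d", seq_len(n)),
      hap1_copies = h1, hap2_copies = h2,
      diploid_mean = (h1 + h2) / 2,
      stringsAsFactors = FALSE)
    class(out) <- c("vntr_cohort", "data.frame")
    out
  })
}

#' Read-simulation configuration
#'
#' @param read_length Read length in nt (100 and 150 are the typical WGS
#'   regimes).
#' @param coverage Mean fold-coverage per haplotype.
#' @param error_rate Per-base substitution probability (no indels are
#'   simulated; the downstream callers tolerate edit distance 2 and
#'   substitutions exercise that tolerance).
#' @param seed Integer seed.
#' @param flank_len Flank window simulated on each side of the array
#'   (default 2000 nt); stands in for a +/- 10 kb read extraction without
#'   simulating a whole genome.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 150L, coverage = 30, error_rate = 0,
                            seed = 1L, flank_len = 2000L) {
  read_length <- as.integer(read_length)
  if (read_length < 45L) {
    stop("read_length must be >= 45 (two 6-bp anchors plus one 33-bp unit)")
  }
  if (coverage <= 0) stop("coverage must be positive")
  if (error_rate < 0 || error_rate >= 0.25) stop("error_rate must be in [0, 0.25)")
  structure(list(read_length = read_length, coverage = coverage,
                 error_rate = error_rate, seed = as.integer(seed),
                 flank_len = as.integer(flank_len)),
            class = "read_sim_config")
}

# Substitute each base with probability `rate` to a uniformly chosen
# different base, vectorized over equal-length reads via raw bytes.
inject_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  widths <- nchar(reads)
  raw <- charToRaw(paste(reads, collapse = ""))
  hit <- which(runif(length(raw)) < rate)
  if (length(hit)) {
    bases <- charToRaw("ACGT")
    cur <- match(raw[hit], bases)
    ok <- !is.na(cur)  # leave non-ACGT untouched
    if (any(ok)) {
      shift <- sample.int(3L, sum(ok), replace = TRUE)
      raw[hit[ok]] <- bases[(cur[ok] - 1L + shift) %% 4L + 1L]
    }
  }
  ends <- cumsum(widths)
  substring(rawToChar(raw), ends - widths + 1L, ends)
}

#' Simulate short reads from one diploid individual
#'
#' For each haplotype, the allele sequence is built with `flank_len` flank
#' bases on each side; `round(coverage * length / read_length)` read start
#' positions are drawn uniformly; each base is substituted with probability
#' `error_rate`; each read is reverse-complemented with probability 0.5.
#' Base qualities are a constant placeholder (`I`) and are never used
#' downstream.
#'
#' @param individual A single-row slice of a [sample_cohort()] data frame
#'   (or any list with `id`, `hap1_copies`, `hap2_copies`).
#' @param locus A [vntr_locus()].
#' @param cfg A [read_sim_config()].
#' @return A list with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `hap`, `copies`, `start`, `strand`).
#' @export
simulate_reads <- function(individual, locus, cfg) {
  stopifnot(inherits(cfg, "read_sim_config"))
  id <- individual$id %||% "ind"
  copies <- c(individual$hap1_copies, individual$hap2_copies)
  with_seed(cfg$seed, {
    reads <- character(0)
    truth <- vector("list", 2L)
    for (h in 1:2) {
      fl <- min(cfg$flank_len, nchar(locus$left_flank_seq))
      fr <- min(cfg$flank_len, nchar(locus$right_flank_seq))
      hap_seq <- build_allele_sequence(locus, copies[h], fl, fr)$seq
      L <- nchar(hap_seq)
      if (L < cfg$read_length) {
        stop("haplotype sequence (", L, " nt) shorter than read_length")
      }
      n_reads <- round(cfg$coverage * L / cfg$read_length)
      starts <- sample.int(L - cfg$read_length + 1L, n_reads, replace = TRUE)
      rd <- substring(hap_seq, starts, starts + cfg$read_length - 1L)
      rd <- inject_errors(rd, cfg$error_rate)
      flip <- runif(n_reads) < 0.5
      if (any(flip)) rd[flip] <- revcomp(rd[flip])
      ids <- sprintf("%s_h%d_r%05d", id, h, seq_len(n_reads))
      names(rd) <- ids
      reads <- c(reads, rd)
      truth[[h]] <- data.frame(
        read_id = ids, hap = h, copies = copies[h], start = starts,
        strand = ifelse(flip, "-", "+"), stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = do.call(rbind, truth))
  })
}

#' Simulate reads for a whole cohort
#'
#' Per-individual seeds are derived deterministically from `cfg$seed` and the
#' individual's index, so adding individuals never perturbs existing ones.
#'
#' @param cohort A [sample_cohort()] data frame.
#' @param locus A [vntr_locus()].
#' @param cfg A [read_sim_config()].
#' @return A list with `reads` (named list: id -> character vector) and
#'   `truth` (combined truth table with an `id` column).
#' @export
simulate_cohort_reads <- function(cohort, locus, cfg) {
  reads <- vector("list", nrow(cohort))
  names(reads) <- cohort$id
  truth <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, i)
    sim <- simulate_reads(cohort[i, ], locus, cfg_i)
    reads[[i]] <- sim$reads
    truth[[i]] <- cbind(id = cohort$id[i], sim$truth, stringsAsFactors = FALSE)
  }
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Simulate a biallelic SNP linked to the VNTR
#'
#' Each haplotype's SNP allele is drawn conditionally on its VNTR allele
#' according to a joint haplotype-frequency table, producing controlled
#' linkage disequilibrium; dosage is the sum over the two haplotypes.
#'
#' @param cohort A [sample_cohort()] data frame.
#' @param hap_freqs Data frame with columns `vntr_allele`, `snp_allele`
#'   (0/1) and `freq`; frequencies must sum to 1 and every VNTR allele
#'   present in the cohort must have positive marginal frequency.
#' @param seed Integer seed.
#' @return Data frame with `id`, `hap1_snp`, `hap2_snp`, `dosage`.
#' @export
simulate_linked_snp <- function(cohort, hap_freqs, seed) {
  need <- c("vntr_allele", "snp_allele", "freq")
  if (!all(need %in% names(hap_freqs))) {
    stop("hap_freqs must have columns vntr_allele, snp_allele, freq")
  }
  if (abs(sum(hap_freqs$freq) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1 (got ",
         format(sum(hap_freqs$freq), digits = 12), ")")
  }
  if (any(hap_freqs$freq < 0)) stop("haplotype frequencies must be non-negative")
  marg <- tapply(hap_freqs$freq, hap_freqs$vntr_allele, sum)
  p1 <- tapply(hap_freqs$freq[hap_freqs$snp_allele == 1],
               hap_freqs$vntr_allele[hap_freqs$snp_allele == 1], sum)
  cond1 <- function(a) {
    key <- as.character(a)
    m <- marg[key]
    if (is.na(m) || m <= 0) {
      stop("cohort VNTR allele ", a, " has zero marginal frequency in hap_freqs")
    }
    p <- p1[key]
    if (is.na(p)) 0 else p / m
  }
  with_seed(seed, {
    draw <- function(hap) {
      probs <- vapply(hap, cond1, numeric(1))
      as.integer(runif(length(hap)) < probs)
    }
    s1 <- draw(cohort$hap1_copies)
    s2 <- draw(cohort$hap2_copies)
    data.frame(id = cohort$id, hap1_snp = s1, hap2_snp = s2,
               dosage = s1 + s2, stringsAsFactors = FALSE)
  })
}

#' Expression-simulation configuration
#'
#' @param n_genes Number of genes (>= 1); gene 1 is the causal gene.
#' @param beta Effect of the diploid-mean copy number on the causal gene's
#'   log2 expression, per copy.
#' @param sigma Residual SD on the log2 scale (> 0).
#' @param baseline Intercept on the log2 scale (default 5, i.e. around 32 in
#'   TPM-like units).
#' @param seed Integer seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes, beta, sigma, baseline = 5, seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L) stop("n_genes must be >= 1")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(n_genes = n_genes, beta = beta, sigma = sigma,
                 baseline = baseline, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate an expression matrix with one causal gene
#'
#' Gene 1 has log2 expression `baseline + beta * diploid_mean + N(0, sigma)`;
#' all other genes are i.i.d. `N(baseline, sigma)` independent of genotype.
#' The matrix is returned on the linear (TPM-like) scale, so the association
#' module's log transform is exercised on realistic input.
#'
#' @param cohort A [sample_cohort()] data frame.
#' @param cfg An [expression_sim_config()].
#' @return Numeric matrix (samples x genes, linear scale) with rownames from
#'   `cohort$id` and an attribute `causal_gene` naming column 1.
#' @export
simulate_expression <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  n <- nrow(cohort)
  with_seed(cfg$seed, {
    logx <- matrix(rnorm(n * cfg$n_genes, mean = cfg$baseline, sd = cfg$sigma),
                   nrow = n, ncol = cfg$n_genes)
    logx[, 1L] <- logx[, 1L] + cfg$beta * cohort$diploid_mean
    x <- 2^logx
    rownames(x) <- cohort$id
    colnames(x) <- sprintf("gene%04d", seq_len(cfg$n_genes))
    attr(x, "causal_gene") <- colnames(x)[1L]
    x
  })
}

#' Variance of the diploid-mean copy number implied by allele frequencies
#'
#' Under Hardy-Weinberg, `var((a1 + a2)/2) = var(a)/2` where `a` is a single
#' haplotype draw.
#'
#' @param freqs Named allele-frequency vector.
#' @return Numeric variance.
#' @export
cohort_cn_variance <- function(freqs) {
  check_freqs(freqs)
  a <- as.numeric(names(freqs))
  m <- sum(a * freqs)
  (sum(a^2 * freqs) - m^2) / 2
}

#' Calibrate the causal effect size to a target population correlation
#'
#' Solves `target_r = beta * sd_cn / sqrt(beta^2 * var_cn + sigma^2)` for `beta`, so a
#' generator can be pinned to a target Pearson correlation between copy
#' number and causal-gene log expression.
#'
#' @param target_r Target population correlation in (0, 1).
#' @param sigma Residual SD of the causal gene's log expression.
#' @param cn_var Variance of the diploid-mean copy number
#'   (see [cohort_cn_variance()]).
#' @return Numeric `beta`.
#' @export
calibrate_effect <- function(target_r, sigma, cn_var) {
  if (target_r <= 0 || target_r >= 1) stop("target_r must be in (0, 1)")
  target_r * sigma / sqrt(cn_var * (1 - target_r^2))
}
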