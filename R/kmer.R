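#' Build the k-mer panel for copy-number estimation
#'
#' The estimator compares the sequencing depth of k-mers inside the repeat
#' unit with k-mers from fixed flank windows. The panel contains:
#' \itemize{
#'   \item the `U - k + 1` within-unit k-mers (step 1), each occurring once
#'     per repeat copy (per-copy multiplicity `c`);
#'   \item if `n_repeat` exceeds that, additional junction k-mers spanning
#'     the unit-to-unit boundary (continuing the step-1 walk along the
#'     tandem array), each occurring `c - 1` times per allele;
#'   \item the `flank_window - k + 1` k-mers from the terminal
#'     `flank_window` bases of each flank (the array-proximal windows); the
#'     default `flank_window = 53` with `k = 25` yields 29 per side.
#' }
#' All k-mers are stored in canonical orientation (lexicographic minimum of
#' the k-mer and its reverse complement). With the defaults (`k = 25`,
#' `n_repeat = 10`) a 33-bp unit contributes 9 within-unit k-mers plus 1
#' junction k-mer; the junction k-mer under-counts 1-copy alleles (it occurs
#' `c - 1` times) but the median over the panel is unaffected, which is why
#' the 10-k-mer default is safe; a `n_repeat = 9` panel is the strictly
#' unbiased choice for 1-copy alleles.
#'
#' @param locus A [vntr_locus()].
#' @param k k-mer length (default 25; must be <= 31).
#' @param n_repeat Number of repeat k-mers (default 10).
#' @param flank_window Flank window length per side (default 53; must be at
#'   least `k`).
#' @return A data frame of class `kmer_panel` with columns `kmer`
#'   (canonical), `class` (`repeat_unit`, `repeat_junction`, `flank5`,
#'   `flank3`), `multiplicity` (`"c"`, `"c-1"`, or `"1"`) and attribute `k`.
#' @export
build_panel <- function(locus, k = 25L, n_repeat = 10L, flank_window = 53L) {
  k <- as.integer(k); n_repeat <- as.integer(n_repeat)
  flank_window <- as.integer(flank_window)
  u <- unit_length(locus)
  if (k > 31L || k < 5L) stop("k must be between 5 and 31")
  if (u < k) stop("repeat unit (", u, " bp) too short for any within-unit ", k, "-mer")
  if (flank_window < k) stop("flank_window must be >= k")
  n_within <- u - k + 1L
  if (n_repeat < 1L) stop("n_repeat must be >= 1")
  if (n_repeat > u) stop("n_repeat cannot exceed the unit length (one period)")

  kmers_of <- function(seq, n) substring(seq, seq_len(n), seq_len(n) + k - 1L)
  lf <- locus$left_flank_seq; rf <- locus$right_flank_seq

  # Array/flank boundary-crossing windows: a panel k-mer that also occurs
  # across a boundary picks up counts its per-copy multiplicity does not
  # account for, so such k-mers are screened out up front.
  lb_cross <- paste0(substr(lf, nchar(lf) - k + 2L, nchar(lf)),
                     substr(locus$unit_seq, 1L, k - 1L))
  rb_cross <- paste0(substr(locus$unit_seq, u - k + 2L, u),
                     substr(rf, 1L, k - 1L))
  crosses_boundary <- function(km) {
    vapply(km, function(x) {
      rc <- revcomp(x)
      grepl(x, lb_cross, fixed = TRUE) || grepl(rc, lb_cross, fixed = TRUE) ||
        grepl(x, rb_cross, fixed = TRUE) || grepl(rc, rb_cross, fixed = TRUE)
    }, logical(1))
  }

  # step-1 walk along the tandem array: offsets <= U - k + 1 lie within one
  # unit (multiplicity c), later offsets span the unit->unit junction
  # (multiplicity c - 1); contaminated k-mers are skipped, the walk continues.
  full_walk <- kmers_of(strrep(locus$unit_seq, 2L), u)
  walk_class <- ifelse(seq_len(u) <= n_within, "repeat_unit", "repeat_junction")
  clean <- !crosses_boundary(full_walk)
  if (!all(clean)) {
    warning(sum(!clean), " repeat k-mer(s) skipped for array-boundary cross-matches")
  }
  take <- which(clean)[seq_len(min(n_repeat, sum(clean)))]
  array_walk <- full_walk[take]
  rep_class <- walk_class[take]
  rep_mult <- ifelse(rep_class == "repeat_unit", "c", "c-1")
  if (nchar(lf) < flank_window || nchar(rf) < flank_window) {
    stop("flanks must be at least flank_window (", flank_window, ") bases long")
  }
  win5 <- substr(lf, nchar(lf) - flank_window + 1L, nchar(lf))
  win3 <- substr(rf, 1L, flank_window)
  f5 <- kmers_of(win5, flank_window - k + 1L)
  f3 <- kmers_of(win3, flank_window - k + 1L)
  bad5 <- crosses_boundary(f5)
  bad3 <- crosses_boundary(f3)
  if (any(bad5) || any(bad3)) {
    warning(sum(bad5) + sum(bad3),
            " flank k-mer(s) skipped for array-boundary cross-matches")
    f5 <- f5[!bad5]
    f3 <- f3[!bad3]
  }

  panel <- data.frame(
    kmer = c(array_walk, f5, f3),
    class = c(rep_class, rep("flank5", length(f5)), rep("flank3", length(f3))),
    multiplicity = c(rep_mult, rep("1", length(f5) + length(f3))),
    stringsAsFactors = FALSE)

  drop_n <- grepl("N", panel$kmer, fixed = TRUE)
  if (any(drop_n)) {
    warning(sum(drop_n), " k-mer(s) containing N dropped from panel")
    panel <- panel[!drop_n, , drop = FALSE]
  }
  panel$kmer <- canonical_kmer(panel$kmer)

  # within-list duplicates collapse to one entry
  panel <- panel[!duplicated(paste(panel$class, panel$kmer)), , drop = FALSE]

  # exact duplicates across lists are a hard error
  is_rep <- panel$class %in% c("repeat_unit", "repeat_junction")
  dup <- intersect(panel$kmer[is_rep], panel$kmer[!is_rep])
  dup <- c(dup, intersect(panel$kmer[panel$class == "flank5"],
                          panel$kmer[panel$class == "flank3"]))
  if (length(dup)) {
    stop("duplicate canonical k-mers across panel lists: ",
         paste(unique(dup), collapse = ", "))
  }

  # cross-uniqueness: a repeat k-mer occurring as a substring of a flank
  # window (either orientation), or vice versa, would double count; drop it.
  occurs_in <- function(km, region) {
    vapply(km, function(x) {
      grepl(x, region, fixed = TRUE) || grepl(revcomp(x), region, fixed = TRUE)
    }, logical(1))
  }
  bad <- logical(nrow(panel))
  flank_region <- paste(win5, win3, sep = "NN")
  rep_region <- strrep(locus$unit_seq, 2L)
  bad[is_rep] <- occurs_in(panel$kmer[is_rep], flank_region)
  bad[!is_rep] <- occurs_in(panel$kmer[!is_rep], rep_region)
  if (any(bad)) {
    warning(sum(bad), " k-mer(s) dropped for repeat/flank cross-matches: ",
            paste(panel$kmer[bad], collapse = ", "))
    panel <- panel[!bad, , drop = FALSE]
  }
  if (!any(panel$class %in% c("repeat_unit", "repeat_junction"))) {
    stop("no repeat k-mers survive panel construction")
  }

  rownames(panel) <- NULL
  attr(panel, "k") <- k
  class(panel) <- c("kmer_panel", "data.frame")
  panel
}

#' Count panel k-mers in a set of reads
#'
#' Every length-`k` window of every read is canonicalized and, when present
#' in the panel, counted; windows containing `N` are skipped. Counting is
#' alignment-free and strand-agnostic, single pass, with memory proportional
#' to the panel size.
#'
#' @param reads Character vector of read sequences, a `DNAStringSet`, or a
#'   FASTQ/FASTA path.
#' @param panel A [build_panel()] result.
#' @return The panel data frame with an added `count` column, of class
#'   `kmer_counts`.
#' @export
count_kmers <- function(reads, panel) {
  stopifnot(inherits(panel, "kmer_panel"))
  reads <- as_reads(reads)
  if (!length(reads)) {
    warning("empty read set: all k-mer counts are zero")
    counts <- rep(0L, nrow(panel))
  } else {
    counts <- cpp_count_kmers(unname(reads), panel$kmer, attr(panel, "k"))
  }
  out <- panel
  out$count <- counts
  class(out) <- c("kmer_counts", "data.frame")
  attr(out, "k") <- attr(panel, "k")
  out
}

#' Estimate diploid-average copy number from k-mer counts
#'
#' Implements the ratio estimator
#' `median(repeat k-mer counts) / max(median(5' flank counts),
#' median(3' flank counts))`. Medians use the standard midpoint rule for
#' even-length lists. Since a flank k-mer occurs once per chromosome while a
#' within-unit repeat k-mer occurs once per repeat copy, the ratio estimates
#' the diploid-average copy number `(c1 + c2) / 2`.
#'
#' @param counts A [count_kmers()] result.
#' @return An object of class `cn_estimate`: list with `value`,
#'   `median_repeat`, `median_flank5`, `median_flank3`.
#' @export
estimate_cn <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  med <- function(cls) {
    x <- counts$count[counts$class %in% cls]
    if (!length(x)) return(NA_real_)
    median(x)
  }
  m_rep <- med(c("repeat_unit", "repeat_junction"))
  m_f5 <- med("flank5")
  m_f3 <- med("flank3")
  denom <- max(m_f5, m_f3, na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0) {
    stop("insufficient flank coverage: both flank medians are zero")
  }
  structure(list(value = m_rep / denom, median_repeat = m_rep,
                 median_flank5 = m_f5, median_flank3 = m_f3),
            class = "cn_estimate")
}

#' @export
print.cn_estimate <- function(x, ...) {
  cat(sprintf("<cn_estimate> %.3f (repeat median %.1f / max flank medians %.1f, %.1f)\n",
              x$value, x$median_repeat, x$median_flank5, x$median_flank3))
  invisible(x)
}

#' Estimate copy number for a cohort of read sets
#'
#' Maps [estimate_cn()] over samples. Per-sample failures (e.g. empty read
#' sets) are recorded as `NA` and the run continues. The result is sorted by
#' estimate, descending, to support screens for the highest-copy-number
#' individuals.
#'
#' @param read_sets Named list; each element is a reads input accepted by
#'   [count_kmers()].
#' @param panel A [build_panel()] result.
#' @return Data frame with columns `sample`, `median_repeat`,
#'   `median_flank5`, `median_flank3`, `cn_estimate`.
#' @export
estimate_cohort <- function(read_sets, panel) {
  if (is.null(names(read_sets))) names(read_sets) <- sprintf("sample%04d", seq_along(read_sets))
  rows <- lapply(names(read_sets), function(s) {
    est <- tryCatch(
      suppressWarnings(estimate_cn(count_kmers(read_sets[[s]], panel))),
      error = function(e) {
        warning("sample ", s, ": ", conditionMessage(e))
        NULL
      })
    data.frame(
      sample = s,
      median_repeat = est$median_repeat %||% NA_real_,
      median_flank5 = est$median_flank5 %||% NA_real_,
      median_flank3 = est$median_flank3 %||% NA_real_,
      cn_estimate = est$value %||% NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$cn_estimate, out$sample, na.last = TRUE), , drop = FALSE]
}
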