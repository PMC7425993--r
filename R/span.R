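#' Spanning-read caller configuration
#'
#' @param max_edit Maximum allowed edit distance between a read and the
#'   expected allele sequence (default 2).
#' @param anchor_len Flank bases required on each side for a full span
#'   (default 6).
#' @param min_partial_fragment Minimum repeat-fragment length, in bases, for
#'   partial-span (open class) evidence (default 6).
#' @param min_allele_reads Minimum supporting reads for an allele to be kept
#'   (default 2; alleles with fewer detections are excluded).
#' @param read_length Read length in nt (default 150).
#' @return A list of class `span_config`.
#' @export
span_config <- function(max_edit = 2L, anchor_len = 6L, min_partial_fragment = 6L,
                        min_allele_reads = 2L, read_length = 150L) {
  cfg <- list(max_edit = as.integer(max_edit), anchor_len = as.integer(anchor_len),
              min_partial_fragment = as.integer(min_partial_fragment),
              min_allele_reads = as.integer(min_allele_reads),
              read_length = as.integer(read_length))
  if (any(vapply(cfg, function(x) is.na(x) || x < 0L, logical(1)))) {
    stop("all span_config fields must be non-negative integers")
  }
  if (cfg$anchor_len < 1L) stop("anchor_len must be >= 1")
  structure(cfg, class = "span_config")
}

#' Maximum copy number fully spannable by a read
#'
#' A full span needs the whole array plus `anchor_len` flank bases on each
#' side, so `C_max = floor((read_length - 2 * anchor_len) / U)`. With 150-bp
#' reads, a 33-bp unit and 6-bp anchors, `C_max = 4`: alleles with 5 or more
#' copies cannot be fully spanned and are reported as the open class
#' `C_max + 1`.
#'
#' @param read_length Read length in nt.
#' @param locus A [vntr_locus()].
#' @param cfg A [span_config()].
#' @return Integer `C_max`.
#' @export
max_fully_spannable <- function(read_length, locus, cfg = span_config()) {
  read_length <- as.integer(read_length)
  if (read_length <= 2L * cfg$anchor_len) {
    stop("read_length must exceed twice the anchor length")
  }
  (read_length - 2L * cfg$anchor_len) %/% unit_length(locus)
}

#' Approximate containment of a pattern in a read
#'
#' Semi-global alignment: the pattern is aligned end to end while the read's
#' ends are free, taking the minimum over both read orientations.
#' `"levenshtein"` mode uses unit-cost substitutions, insertions and
#' deletions; `"hamming"` is a substitution-only mode for sensitivity
#' analysis.
#'
#' @param read Read sequence (non-empty string).
#' @param pattern Expected sequence (non-empty string).
#' @param max_edit Maximum tolerated distance.
#' @param mode `"levenshtein"` (default) or `"hamming"`.
#' @return Integer best distance if `<= max_edit`, otherwise `NA`.
#' @export
approx_contains <- function(read, pattern, max_edit = 2L, mode = c("levenshtein", "hamming")) {
  mode <- match.arg(mode)
  if (!nzchar(pattern)) stop("pattern must be non-empty")
  read <- toupper(read); pattern <- toupper(pattern)
  dist_fun <- if (mode == "levenshtein") cpp_edit_semiglobal else cpp_hamming_min
  d <- min(dist_fun(pattern, read), dist_fun(pattern, revcomp(read)))
  if (d <= max_edit) as.integer(d) else NA_integer_
}

# Full-span patterns for c = 1..C_max plus the open-class partial patterns
# and their flank-explained guards.
span_patterns <- function(locus, cfg, read_length = cfg$read_length) {
  u <- locus$unit_seq
  a <- cfg$anchor_len
  f <- cfg$min_partial_fragment
  lf <- locus$left_flank_seq; rf <- locus$right_flank_seq
  c_max <- max_fully_spannable(read_length, locus, cfg)
  if (c_max < 1L) stop("read_length cannot span even a single repeat copy")
  left_a <- substr(lf, nchar(lf) - a + 1L, nchar(lf))
  right_a <- substr(rf, 1L, a)
  core <- strrep(u, c_max)
  list(
    c_max = c_max,
    full = vapply(seq_len(c_max),
                  function(c) paste0(left_a, strrep(u, c), right_a), character(1)),
    pl = paste0(substr(u, nchar(u) - f + 1L, nchar(u)), core),
    plf = paste0(substr(lf, nchar(lf) - f + 1L, nchar(lf)), core),
    pr = paste0(core, substr(u, 1L, f)),
    prf = paste0(core, substr(rf, 1L, f)))
}

#' Call allele evidence for reads
#'
#' Two-pass caller per read:
#' \enumerate{
#'   \item full-span pass: for each `c` in `1..C_max` the expected pattern is
#'     `anchor_len` left-flank bases + `c` units + `anchor_len` right-flank
#'     bases; a read matching exactly one pattern within `max_edit`
#'     (either orientation) yields evidence for allele `c`. Patterns for
#'     distinct `c` differ by about a full unit, so at most one can match.
#'   \item open-class pass: a read with no full-span match that carries
#'     `C_max` full units plus an adjacent repeat fragment of at least
#'     `min_partial_fragment` bases (within `max_edit` overall), where the
#'     fragment is \emph{not} explainable as flank sequence within
#'     `max_edit`, yields evidence for the open class `C_max + 1`
#'     (label 5 for 150-bp reads).
#' }
#'
#' @param reads Character vector of read sequences (or reads input accepted
#'   by [count_kmers()]).
#' @param locus A [vntr_locus()].
#' @param cfg A [span_config()].
#' @return Integer vector, one element per read: allele evidence `c`, the
#'   open-class label `C_max + 1`, or `NA` for reads yielding no evidence.
#' @export
call_reads <- function(reads, locus, cfg = span_config()) {
  reads <- toupper(as_reads(reads))
  p <- span_patterns(locus, cfg)
  ev <- cpp_call_reads(unname(reads), p$full, p$pl, p$plf, p$pr, p$prf,
                       cfg$max_edit, p$c_max + 1L)
  if (any(ev == -1L)) {
    warning(sum(ev == -1L), " read(s) matched two full-span patterns; dropped")
    ev[ev == -1L] <- 0L
  }
  ev[ev == 0L] <- NA_integer_
  ev
}

#' Call allele evidence for a single read
#'
#' Scalar convenience wrapper around [call_reads()].
#'
#' @inheritParams call_reads
#' @param read A single read sequence.
#' @return A list with `allele` (integer) or `NULL` when the read yields no
#'   evidence.
#' @export
call_read <- function(read, locus, cfg = span_config()) {
  ev <- call_reads(read, locus, cfg)
  if (is.na(ev[1L])) return(NULL)
  list(allele = ev[1L])
}

#' Genotype one sample from spanning-read evidence
#'
#' Aggregates [call_reads()] evidence into per-allele read counts, drops
#' alleles supported by fewer than `min_allele_reads` reads, and classifies
#' the sample: two surviving alleles give a heterozygous call, one gives a
#' single-allele call (treated as homozygous for frequency purposes, and
#' flagged), more than two give `excluded_multiallelic`, none gives
#' `no_call`.
#'
#' @inheritParams call_reads
#' @param sample_id Sample identifier stored in the result.
#' @return An object of class `sample_genotype`: list with `sample`,
#'   `status` (`"called"`, `"no_call"`, `"excluded_multiallelic"`),
#'   `alleles` (sorted integer vector, length 1-2), `counts` (supporting
#'   reads per surviving allele), `single_allele` flag, and `evidence` (all
#'   pre-filter counts).
#' @export
genotype_sample <- function(reads, locus, cfg = span_config(), sample_id = "sample") {
  ev <- call_reads(reads, locus, cfg)
  ev <- ev[!is.na(ev)]
  evidence <- table(ev)
  counts <- as.integer(evidence)
  names(counts) <- names(evidence)
  keep <- counts[counts >= cfg$min_allele_reads]
  status <- if (length(keep) == 0L) "no_call"
  else if (length(keep) > 2L) "excluded_multiallelic"
  else "called"
  alleles <- if (status == "called") sort(as.integer(names(keep))) else integer(0)
  structure(list(
    sample = sample_id, status = status, alleles = alleles,
    counts = if (status == "called") as.integer(keep[order(as.integer(names(keep)))]) else integer(0),
    single_allele = status == "called" && length(alleles) == 1L,
    evidence = counts), class = "sample_genotype")
}

#' @export
print.sample_genotype <- function(x, ...) {
  al <- if (length(x$alleles)) paste(x$alleles, collapse = "/") else "-"
  cat(sprintf("<sample_genotype> %s: %s (%s)%s\n", x$sample, x$status, al,
              if (isTRUE(x$single_allele)) " [single allele]" else ""))
  invisible(x)
}

#' Genotype a cohort of read sets
#'
#' @param read_sets Named list; each element a reads input for
#'   [genotype_sample()].
#' @inheritParams call_reads
#' @return Data frame with columns `sample`, `status`, `allele1`, `allele2`,
#'   `reads1`, `reads2`, `single_allele`, `evidence_json` (raw pre-filter
#'   evidence as JSON).
#' @export
genotype_cohort <- function(read_sets, locus, cfg = span_config()) {
  if (is.null(names(read_sets))) names(read_sets) <- sprintf("sample%04d", seq_along(read_sets))
  rows <- lapply(names(read_sets), function(s) {
    g <- genotype_sample(read_sets[[s]], locus, cfg, sample_id = s)
    a1 <- if (length(g$alleles) >= 1L) g$alleles[1L] else NA_integer_
    a2 <- if (length(g$alleles) >= 2L) g$alleles[2L] else NA_integer_
    data.frame(
      sample = s, status = g$status, allele1 = a1, allele2 = a2,
      reads1 = if (length(g$counts) >= 1L) g$counts[1L] else NA_integer_,
      reads2 = if (length(g$counts) >= 2L) g$counts[2L] else NA_integer_,
      single_allele = isTRUE(g$single_allele),
      evidence_json = as.character(jsonlite::toJSON(as.list(g$evidence), auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan reads for evidence of six or more repeat copies
#'
#' Flags reads that contain `n_units` (default 4) consecutive full repeat
#' units with repeat-consistent partial matches of at least
#' `min_partial_fragment` bases at \emph{both} ends, neither partial
#' explainable as flank sequence within `max_edit`. With no flank present, a
#' partial on each side of a 4-unit run implies at least 6 distinct copies; a
#' 5-copy array cannot produce such a read, so flags are evidence for a
#' hypothetical allele of 6 or more copies. A partial at only one end is
#' already explained by a 5-copy allele, hence the both-ends requirement.
#'
#' @inheritParams call_reads
#' @param n_units Number of consecutive full units required (default 4).
#' @return Character vector of flagged read ids (or indices when reads are
#'   unnamed).
#' @export
scan_six_plus <- function(reads, locus, cfg = span_config(), n_units = 4L) {
  u <- locus$unit_seq
  f <- cfg$min_partial_fragment
  need <- n_units * unit_length(locus) + 2L * f
  if (cfg$read_length < need) {
    stop("read_length (", cfg$read_length, ") too short for the >=6-copy scan (needs ",
         need, ")")
  }
  reads <- toupper(as_reads(reads))
  core <- strrep(u, n_units)
  lf <- locus$left_flank_seq; rf <- locus$right_flank_seq
  pb <- paste0(substr(u, nchar(u) - f + 1L, nchar(u)), core, substr(u, 1L, f))
  pbl <- paste0(substr(lf, nchar(lf) - f + 1L, nchar(lf)), core, substr(u, 1L, f))
  pbr <- paste0(substr(u, nchar(u) - f + 1L, nchar(u)), core, substr(rf, 1L, f))
  flag <- cpp_scan_six(unname(reads), pb, pbl, pbr, cfg$max_edit)
  ids <- names(reads) %||% as.character(seq_along(reads))
  ids[flag]
}
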