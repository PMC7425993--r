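#' Define a VNTR locus
#'
#' A `vntr_locus` is the single source of truth for all sequence construction
#' in the package: the repeat unit, the immediate flanking sequences, and the
#' reference coordinates of the repeat array. Coordinates follow the 1-based
#' inclusive convention used in genome browsers and locus configs.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive genomic coordinates of the reference
#'   repeat array; `end - start + 1` must equal
#'   `nchar(unit_seq) * ref_copies`.
#' @param unit_seq Repeat-unit nucleotide string (unit length must be >= 7,
#'   the defining property of a VNTR; no `N` allowed).
#' @param left_flank_seq,right_flank_seq Sequence immediately 5' / 3' of the
#'   array. At least 200 nt each is recommended so that read simulation and
#'   k-mer normalization have representative flank sequence to work with.
#' @param ref_copies Integer copy number of the repeat in the reference
#'   genome.
#' @return An object of class `vntr_locus`.
#' @examples
#' loc <- synthetic_locus(seed = 1, flank_len = 300)
#' loc
#' @export
vntr_locus <- function(chrom, start, end, unit_seq, left_flank_seq,
                       right_flank_seq, ref_copies) {
  unit_seq <- toupper(unit_seq)
  left_flank_seq <- toupper(left_flank_seq)
  right_flank_seq <- toupper(right_flank_seq)
  start <- as.integer(start)
  end <- as.integer(end)
  ref_copies <- as.integer(ref_copies)
  u <- nchar(unit_seq)
  if (u < 7L) {
    stop("repeat unit must be at least 7 bp (VNTR definition); got ", u)
  }
  if (!is_dna(unit_seq, allow_n = FALSE)) {
    stop("unit_seq must contain only A/C/G/T (no N)")
  }
  if (!is_dna(left_flank_seq) || !is_dna(right_flank_seq)) {
    stop("flank sequences may contain only A/C/G/T/N")
  }
  if (ref_copies < 1L) stop("ref_copies must be >= 1")
  if (end - start + 1L != u * ref_copies) {
    stop(sprintf(
      "coordinate span (%d) does not equal unit length x ref_copies (%d x %d = %d)",
      end - start + 1L, u, ref_copies, u * ref_copies))
  }
  structure(
    list(chrom = chrom, start = start, end = end, unit_seq = unit_seq,
         left_flank_seq = left_flank_seq, right_flank_seq = right_flank_seq,
         ref_copies = ref_copies),
    class = "vntr_locus")
}

#' @export
print.vntr_locus <- function(x, ...) {
  cat(sprintf("<vntr_locus> %s:%d-%d (1-based inclusive)\n", x$chrom, x$start, x$end))
  cat(sprintf("  unit: %d bp, reference copies: %d\n", nchar(x$unit_seq), x$ref_copies))
  cat(sprintf("  flanks: %d bp (5'), %d bp (3')\n",
              nchar(x$left_flank_seq), nchar(x$right_flank_seq)))
  invisible(x)
}

unit_length <- function(locus) nchar(locus$unit_seq)

#' Convert locus coordinates to 0-based half-open
#'
#' Locus configs store 1-based inclusive coordinates; this is the single
#' converter to the 0-based half-open convention used by BED-style interop.
#'
#' @param locus A [vntr_locus()].
#' @return A list with `chrom`, `start` (0-based) and `end` (exclusive).
#' @export
coords_0based <- function(locus) {
  list(chrom = locus$chrom, start = locus$start - 1L, end = locus$end)
}

#' Construct an allele sequence for a given copy number
#'
#' Builds `left flank tail + c repeat units + right flank head`, the sequence
#' of a hypothetical allele carrying `c` copies of the repeat unit.
#'
#' @param locus A [vntr_locus()].
#' @param c Non-negative integer copy number.
#' @param left_len,right_len How many flank bases to include on each side
#'   (taken from the array-proximal ends of the stored flanks).
#' @return An object of class `allele_sequence`: a list with `copy_number`
#'   and `seq`.
#' @examples
#' loc <- synthetic_locus(seed = 1, flank_len = 300)
#' nchar(build_allele_sequence(loc, 3, 23, 33)$seq)  # 23 + 3*33 + 33 = 155
#' @export
build_allele_sequence <- function(locus, c, left_len, right_len) {
  c <- as.integer(c)
  left_len <- as.integer(left_len)
  right_len <- as.integer(right_len)
  if (is.na(c) || c < 0L) stop("copy number c must be a non-negative integer")
  if (left_len < 0L || right_len < 0L) stop("flank lengths must be non-negative")
  lf <- locus$left_flank_seq
  rf <- locus$right_flank_seq
  if (left_len > nchar(lf)) {
    stop("requested left flank (", left_len, ") exceeds available (", nchar(lf), ")")
  }
  if (right_len > nchar(rf)) {
    stop("requested right flank (", right_len, ") exceeds available (", nchar(rf), ")")
  }
  seq <- paste0(
    substr(lf, nchar(lf) - left_len + 1L, nchar(lf)),
    strrep(locus$unit_seq, c),
    substr(rf, 1L, right_len))
  structure(list(copy_number = c, seq = seq), class = "allele_sequence")
}

#' Predict PCR amplicon length for a copy number
#'
#' Amplicons from primers flanking the array contain, in addition to the
#' repeats, fixed up- and downstream fragments (defaults 23 bp and 33 bp),
#' so a gel ladder maps directly to copy number.
#'
#' @param locus A [vntr_locus()].
#' @param c Non-negative integer copy number.
#' @param up,down Non-repeat bases contributed by the amplicon upstream /
#'   downstream of the array.
#' @return Integer amplicon length `U * c + up + down`.
#' @examples
#' loc <- synthetic_locus(seed = 1, flank_len = 300)
#' predict_amplicon_length(loc, 2)  # 122
#' @export
predict_amplicon_length <- function(locus, c, up = 23L, down = 33L) {
  c <- as.integer(c)
  if (is.na(c) || c < 0L) stop("copy number c must be a non-negative integer")
  unit_length(locus) * c + as.integer(up) + as.integer(down)
}

#' Locate CARE motifs in a repeat unit
#'
#' Searches the forward strand for the C/EBP-ATF response element (CARE)
#' consensus `TT(G/A)CATCA`, the regulatory motif that makes repeat copy
#' number functionally relevant: each extra unit adds one response element.
#'
#' @param unit Nucleotide string (typically `locus$unit_seq`).
#' @return Integer vector of 0-based match offsets (empty when absent).
#' @examples
#' find_care_motifs(synthetic_locus(seed = 1, flank_len = 300)$unit_seq)  # 13
#' @export
find_care_motifs <- function(unit) {
  if (!nzchar(unit)) stop("unit must be non-empty")
  m <- gregexpr("TT[GA]CATCA", toupper(unit))[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Generate the synthetic fixture locus
#'
#' The real promoter unit and flank sequences are not shipped; this builds a
#' reproducible stand-in with the same structural parameters: a random 33-bp
#' unit carrying the CARE motif `TTGCATCA` at 0-based offset 13 (unit
#' positions 14-21), three reference copies spanning a 99-bp array, and
#' random flanks. Users supply real sequences via FASTA plus a JSON config
#' ([read_locus_config()]).
#'
#' @param seed Integer seed (the fixture is fully determined by it).
#' @param flank_len Length of each simulated flank (default 2000, so that
#'   read simulation has a window standing in for a +/- 10 kb extraction).
#' @return A [vntr_locus()].
#' @export
synthetic_locus <- function(seed = 101L, flank_len = 2000L) {
  with_seed(seed, {
    rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
    repeat {
      unit <- paste0(rand_dna(13L), "TTGCATCA", rand_dna(12L))
      if (identical(find_care_motifs(unit), 13L)) break
    }
    vntr_locus(
      chrom = "chr20", start = 380879L, end = 380977L,
      unit_seq = unit,
      left_flank_seq = rand_dna(flank_len),
      right_flank_seq = rand_dna(flank_len),
      ref_copies = 3L)
  })
}

#' Read a locus definition from a JSON config plus FASTA files
#'
#' The config is a JSON object with fields `chrom`, `start`, `end`,
#' `ref_copies`, and FASTA paths `unit_fasta`, `left_flank_fasta`,
#' `right_flank_fasta` (relative paths are resolved against the config's
#' directory).
#'
#' @param path Path to the JSON config.
#' @return A [vntr_locus()].
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) stop("locus config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("chrom", "start", "end", "ref_copies", "unit_fasta",
            "left_flank_fasta", "right_flank_fasta")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("locus config missing fields: ", paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  read_one <- function(p) {
    p <- resolve(p)
    if (!file.exists(p)) stop("locus FASTA not found: ", p)
    s <- Biostrings::readDNAStringSet(p)
    if (length(s) < 1L) stop("empty FASTA: ", p)
    as.character(s[[1L]])
  }
  vntr_locus(
    chrom = cfg$chrom, start = cfg$start, end = cfg$end,
    unit_seq = read_one(cfg$unit_fasta),
    left_flank_seq = read_one(cfg$left_flank_fasta),
    right_flank_seq = read_one(cfg$right_flank_fasta),
    ref_copies = cfg$ref_copies)
}

#' Write a locus definition as a JSON config plus FASTA files
#'
#' Inverse of [read_locus_config()]; used by the pipeline to echo its locus
#' and to build fixtures.
#'
#' @param locus A [vntr_locus()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the emitted files.
#' @return Path to the written JSON config, invisibly.
#' @export
write_locus_config <- function(locus, dir, name = "locus") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fa <- function(seq, id, file) {
    writeLines(c(paste0(">", id), seq), file.path(dir, file))
    file
  }
  cfg <- list(
    chrom = locus$chrom, start = locus$start, end = locus$end,
    ref_copies = locus$ref_copies,
    unit_fasta = write_fa(locus$unit_seq, "repeat_unit", paste0(name, "_unit.fa")),
    left_flank_fasta = write_fa(locus$left_flank_seq, "left_flank",
                                paste0(name, "_left_flank.fa")),
    right_flank_fasta = write_fa(locus$right_flank_seq, "right_flank",
                                 paste0(name, "_right_flank.fa")))
  out <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(cfg, out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
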