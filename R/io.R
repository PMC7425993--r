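# Read/write of standard sequence formats; thin wrappers over Biostrings /
# Rsamtools so the rest of the package works with plain character vectors.

#' Write reads to a FASTQ file
#'
#' @param reads Named character vector of read sequences (names become read
#'   ids; unnamed reads get sequential ids).
#' @param path Output path (plain text; use a `.gz` extension for gzip).
#' @param qual Constant quality character used for every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), unname(reads), "+",
                             strrep(qual, nchar(reads)))), con)
  invisible(path)
}

#' Read sequences from a FASTQ or FASTA file
#'
#' @param path Path to a FASTQ/FASTA file (optionally gzip-compressed).
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path, format = "fastq") {
  if (!file.exists(path)) stop("read file not found: ", path)
  s <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Extract reads overlapping a region from a coordinate-sorted BAM
#'
#' Front-end convenience only: reads are extracted (with a padding window,
#' default +/- 10 kb) and handed to the alignment-free counters/callers;
#' alignments themselves are never used. Requires the `Rsamtools` package.
#'
#' @param bam Path to an indexed BAM file.
#' @param locus A [vntr_locus()] providing the region.
#' @param pad Padding in bp on each side of the array.
#' @return Named character vector of read sequences.
#' @export
extract_reads_bam <- function(bam, locus, pad = 10000L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("extract_reads_bam requires the Rsamtools package")
  }
  which <- GenomicRanges::GRanges(
    locus$chrom,
    IRanges::IRanges(max(1L, locus$start - pad), locus$end + pad))
  prm <- Rsamtools::ScanBamParam(what = c("qname", "seq"), which = which)
  res <- Rsamtools::scanBam(bam, param = prm)[[1L]]
  out <- as.character(res$seq)
  names(out) <- res$qname
  out
}

# Coerce reads input (character vector, DNAStringSet, or FASTQ/FASTA path)
# to a character vector of sequences.
as_reads <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", x, ignore.case = TRUE)) {
    return(read_fastq(x))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fasta|fa)(\\.gz)?$", x, ignore.case = TRUE)) {
    return(read_fastq(x, format = "fasta"))
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) return(x)
  stop("cannot interpret reads input of class ", paste(class(x), collapse = "/"))
}
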