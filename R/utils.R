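# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators never perturb user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a 31-bit sub-seed from a global seed and integer
# stream labels, so per-sample substreams are stable when samples are added.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 12345) %% 2147483647
  as.integer(h)
}

is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  all(grepl(pat, x))
}

revcomp <- function(x) {
  as.character(cpp_revcomp(as.character(x)))
}

canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

write_tsv0 <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv0 <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
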