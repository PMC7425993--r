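#' Population allele frequencies from called genotypes
#'
#' Excluded and no-call samples are dropped; called heterozygotes contribute
#' one copy of each allele and single-allele calls contribute two copies of
#' that allele (treated as homozygous).
#'
#' @param genotypes Data frame as produced by [genotype_cohort()] (columns
#'   `sample`, `status`, `allele1`, `allele2`).
#' @param populations Either a character vector aligned with `genotypes`
#'   rows, or a data frame with columns `sample` and `population`. Defaults
#'   to a single population `"all"`.
#' @return Object of class `allele_freq_table`: list with `freqs`
#'   (population -> named frequency vector) and `n` (population -> number of
#'   called individuals).
#' @export
allele_frequencies <- function(genotypes, populations = NULL) {
  if (is.null(populations)) {
    pop <- rep("all", nrow(genotypes))
  } else if (is.data.frame(populations)) {
    pop <- populations$population[match(genotypes$sample, populations$sample)]
    if (anyNA(pop)) stop("population map missing samples: ",
                         paste(genotypes$sample[is.na(pop)], collapse = ", "))
  } else {
    stopifnot(length(populations) == nrow(genotypes))
    pop <- as.character(populations)
  }
  freqs <- list(); sizes <- integer(0)
  for (p in unique(pop)) {
    g <- genotypes[pop == p & genotypes$status == "called", , drop = FALSE]
    if (!nrow(g)) {
      warning("population ", p, " has no called samples; dropped")
      next
    }
    copies <- c(g$allele1, ifelse(is.na(g$allele2), g$allele1, g$allele2))
    tab <- table(copies)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    freqs[[p]] <- f
    sizes[p] <- nrow(g)
  }
  structure(list(freqs = freqs, n = sizes), class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("<allele_freq_table>", length(x$freqs), "population(s)\n")
  for (p in names(x$freqs)) {
    cat(sprintf("  %s (n=%d): %s\n", p, x$n[[p]],
                paste(sprintf("%s:%.3f", names(x$freqs[[p]]), x$freqs[[p]]),
                      collapse = " ")))
  }
  invisible(x)
}

#' Expected heterozygosity of an allele-frequency vector
#'
#' `H = 1 - sum(p_i^2)`, the probability that two random gene copies differ.
#'
#' @param p Numeric frequency vector summing to 1.
#' @return Numeric in `[0, 1)`.
#' @examples
#' expected_heterozygosity(c(0.5, 0.5))  # 0.5
#' @export
expected_heterozygosity <- function(p) {
  if (any(p < 0)) stop("frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) {
    stop("frequency vector must sum to 1 (got ", format(sum(p), digits = 12), ")")
  }
  1 - sum(p^2)
}

# Align two population frequency vectors on the union of allele labels,
# absent alleles at frequency 0.
align_freqs <- function(fa, fb) {
  labels <- sort(unique(c(names(fa), names(fb))))
  a <- stats::setNames(rep(0, length(labels)), labels)
  b <- a
  a[names(fa)] <- fa
  b[names(fb)] <- fb
  list(a = a, b = b)
}

#' Pairwise multi-allelic fixation index
#'
#' Nei-style G_ST on mean allele frequencies:
#' `H_S` is the (weighted) mean within-population expected heterozygosity,
#' `H_T = 1 - sum(p_bar^2)` the total heterozygosity of the mean frequency
#' vector, and `F_ST = (H_T - H_S) / H_T`. Populations are weighted equally
#' by default, or by sample size with `weighting = "by_n"`. No small-sample
#' bias correction is applied by default; `bias_correct = TRUE` applies the
#' `2n/(2n - 1)` within-population correction (requires sample sizes).
#'
#' @param table An [allele_frequencies()] result.
#' @param popA,popB Population names present in the table.
#' @param weighting `"equal"` (default) or `"by_n"`.
#' @param bias_correct Apply the within-population small-sample correction.
#' @return Object of class `fst_result`: list with `pop_pair`, `H_S`, `H_T`,
#'   `fst`, and `undefined` flag (TRUE when `H_T = 0`, in which case `fst`
#'   is `NA`).
#' @export
pairwise_fst <- function(table, popA, popB, weighting = c("equal", "by_n"),
                         bias_correct = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(table, "allele_freq_table"))
  if (!popA %in% names(table$freqs) || !popB %in% names(table$freqs)) {
    stop("both populations must be present in the frequency table")
  }
  al <- align_freqs(table$freqs[[popA]], table$freqs[[popB]])
  w <- if (weighting == "equal") c(0.5, 0.5) else {
    ns <- c(table$n[[popA]], table$n[[popB]])
    ns / sum(ns)
  }
  h <- c(expected_heterozygosity(al$a), expected_heterozygosity(al$b))
  if (bias_correct) {
    nn <- 2 * c(table$n[[popA]], table$n[[popB]])
    h <- h * nn / (nn - 1)
  }
  hs <- sum(w * h)
  pbar <- w[1] * al$a + w[2] * al$b
  ht <- 1 - sum(pbar^2)
  undefined <- ht <= 0
  structure(list(pop_pair = c(popA, popB), H_S = hs, H_T = ht,
                 fst = if (undefined) NA_real_ else (ht - hs) / ht,
                 undefined = undefined),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> %s vs %s: F_ST = %s (H_S = %.4f, H_T = %.4f)\n",
              x$pop_pair[1], x$pop_pair[2],
              if (x$undefined) "undefined (H_T = 0)" else sprintf("%.4f", x$fst),
              x$H_S, x$H_T))
  invisible(x)
}

#' Pairwise F_ST matrix over all populations
#'
#' @inheritParams pairwise_fst
#' @return Symmetric numeric matrix with zero diagonal; entries are `NA`
#'   where the pairwise index is undefined (both populations fixed for the
#'   same allele).
#' @export
fst_matrix <- function(table, weighting = c("equal", "by_n"), bias_correct = FALSE) {
  weighting <- match.arg(weighting)
  pops <- names(table$freqs)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (length(pops) >= 2L) {
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in (i + 1L):length(pops)) {
        fst <- pairwise_fst(table, pops[i], pops[j], weighting, bias_correct)$fst
        m[i, j] <- m[j, i] <- fst
      }
    }
  }
  m
}
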