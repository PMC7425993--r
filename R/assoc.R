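#' Log-transform an expression matrix
#'
#' Elementwise `log_base(x + offset)` of depth-normalized (TPM/FPKM-like)
#' expression values.
#'
#' @param x Non-negative numeric matrix or vector.
#' @param offset Pseudo-count added before the log (default 1).
#' @param base Logarithm base: 2 (default), `exp(1)`, or 10.
#' @return Transformed matrix/vector.
#' @export
log_transform <- function(x, offset = 1, base = 2) {
  if (any(x < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  log(x + offset, base = base)
}

# Benjamini-Hochberg adjustment; kept as an explicit implementation so the
# test suite can check it against an independent reference.
bh_adjust <- function(p) {
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

pearson_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n, untestable = TRUE))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, untestable = TRUE))
  }
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n, untestable = FALSE)
}

#' Transcriptome-wide correlation of copy number with expression
#'
#' Per-gene Pearson correlation (two-sided p from the t approximation)
#' between a per-sample copy-number value and log-expression, with
#' Benjamini-Hochberg q-values computed across all testable genes (genes
#' with fewer than 3 paired samples or zero variance are flagged untestable
#' and excluded from the FDR family).
#'
#' @param cn Named numeric vector of per-sample copy-number values.
#' @param expr Numeric matrix of log expression, samples x genes, with
#'   rownames matching `names(cn)`.
#' @return Data frame with `gene`, `n`, `r`, `p`, `q`, `untestable`, sorted
#'   by `p`.
#' @export
correlate_cn_expression <- function(cn, expr) {
  if (is.null(rownames(expr)) || is.null(names(cn))) {
    stop("cn must be named and expr must have rownames (sample ids)")
  }
  common <- intersect(names(cn), rownames(expr))
  if (length(common) < 3L) stop("need at least 3 overlapping samples")
  cnv <- cn[common]
  em <- expr[common, , drop = FALSE]
  res <- lapply(colnames(em), function(g) {
    t <- pearson_test(cnv, em[, g])
    data.frame(gene = g, n = t$n, r = t$r, p = t$p, untestable = t$untestable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  testable <- !out$untestable
  out$q[testable] <- bh_adjust(out$p[testable])
  out <- out[order(out$p), c("gene", "n", "r", "p", "q", "untestable")]
  rownames(out) <- NULL
  out
}

#' Per-tissue correlation screen for one gene
#'
#' Computes the copy-number/expression Pearson correlation for a named gene
#' in each tissue, FDR-adjusted across tissues (a separate family from the
#' transcriptome-wide screen). Tissues with fewer than `min_samples`
#' overlapping samples, or missing the gene, are dropped with a warning.
#'
#' @param cn Named numeric vector of per-sample copy-number values.
#' @param tissues Named list of expression matrices (samples x genes, linear
#'   scale; log-transformed internally with `log2(x + 1)` unless
#'   `log = FALSE`).
#' @param gene Gene (column) name to test.
#' @param min_samples Minimum overlapping samples per tissue (default 5).
#' @param log Log-transform tissue matrices before testing (default TRUE).
#' @return Data frame with `tissue`, `n`, `r`, `p`, `q`.
#' @export
tissue_screen <- function(cn, tissues, gene, min_samples = 5L, log = TRUE) {
  rows <- list()
  for (tn in names(tissues)) {
    em <- tissues[[tn]]
    if (!gene %in% colnames(em)) {
      warning("tissue ", tn, " lacks gene ", gene, "; dropped")
      next
    }
    common <- intersect(names(cn), rownames(em))
    if (length(common) < min_samples) {
      warning("tissue ", tn, " has ", length(common), " samples (< ",
              min_samples, "); dropped")
      next
    }
    y <- em[common, gene]
    if (log) y <- log_transform(y)
    t <- pearson_test(cn[common], y)
    rows[[tn]] <- data.frame(tissue = tn, n = t$n, r = t$r, p = t$p,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no tissue passed the inclusion criteria")
    return(data.frame(tissue = character(0), n = integer(0), r = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' SNP allele-effect linear regression
#'
#' Ordinary least squares of a response (log expression or a copy-number
#' estimate) on SNP dosage with an intercept; the reported p-value is the
#' two-sided t-test on the slope.
#'
#' @param dosage Numeric vector of allele dosages (0/1/2).
#' @param y Numeric response vector of the same length.
#' @return Object of class `regression_result`: list with `beta`, `se`, `t`,
#'   `p`, `n`.
#' @export
dosage_effect <- function(dosage, y) {
  ok <- stats::complete.cases(dosage, y)
  dosage <- dosage[ok]; y <- y[ok]
  n <- length(dosage)
  if (n < 3L) stop("need at least 3 samples")
  if (length(unique(dosage)) < 2L) stop("no allele variation: dosage is constant")
  fit <- stats::lm(y ~ dosage)
  sm <- summary(fit)$coefficients
  structure(list(beta = unname(sm["dosage", "Estimate"]),
                 se = unname(sm["dosage", "Std. Error"]),
                 t = unname(sm["dosage", "t value"]),
                 p = unname(sm["dosage", "Pr(>|t|)"]),
                 n = n), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> beta = %.4g (se %.3g), t = %.3g, p = %.3g, n = %d\n",
              x$beta, x$se, x$t, x$p, x$n))
  invisible(x)
}

#' Composite linkage disequilibrium r-squared between dosage vectors
#'
#' Squared Pearson correlation of unphased genotype dosages (composite LD).
#'
#' @param dosA,dosB Numeric dosage vectors (0/1/2) of equal length.
#' @return Numeric in `[0, 1]`, or `NA` (with a warning) when either vector
#'   is constant.
#' @export
ld_r2 <- function(dosA, dosB) {
  ok <- stats::complete.cases(dosA, dosB)
  a <- dosA[ok]; b <- dosB[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant dosage vector: LD r^2 undefined")
    return(NA_real_)
  }
  cor(a, b)^2
}
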