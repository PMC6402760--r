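#' Length and G+C composition of sequences
#'
#' G+C fraction is computed as (G + C) / (A + C + G + T): N bases are
#' excluded from the denominator so database sequences with ambiguity
#' padding do not bias the estimate. A sequence consisting only of Ns
#' has no defined G+C content and is an error.
#'
#' @param x A character vector of sequences, a \code{DNAStringSet}, or
#'   a \linkS4class{UtrCatalog} (its records are summarised).
#' @return A \code{DataFrame} with columns \code{length},
#'   \code{gc_fraction} and \code{gc_percent} (one row per sequence);
#'   \code{gc_percent} is exactly 100 * \code{gc_fraction}.
#' @examples
#' gcContent(c("ATGC", "GGCC"))
#' @export
gcContent <- function(x) {
  if (is(x, "UtrCatalog")) x <- catalogSequences(x)
  if (is(x, "DNAStringSet")) x <- as.character(x)
  seqs <- vapply(x, .normalizeSeq, character(1), USE.NAMES = FALSE)
  freq <- t(vapply(seqs, function(s) {
    ch <- .seqChars(s)
    c(sum(ch %in% c("G", "C")), sum(ch %in% c("A", "C", "G", "T")))
  }, numeric(2), USE.NAMES = FALSE))
  if (any(freq[, 2L] == 0))
    stop("G+C content undefined: sequence of only Ns")
  S4Vectors::DataFrame(
    length = nchar(seqs),
    gc_fraction = freq[, 1L] / freq[, 2L],
    gc_percent = 100 * freq[, 1L] / freq[, 2L],
    row.names = if (is.null(names(x))) NULL else names(x))
}

#' G+C content at chosen codon positions of a CDS
#'
#' The reading frame starts at the first base. A trailing partial codon
#' is ignored with a warning. Ns are excluded from the denominator.
#'
#' @param cds Coding sequence (character scalar).
#' @param position Codon position(s): \code{"1"}, \code{"2"},
#'   \code{"3"}, or \code{"12"} (positions 1 and 2 pooled).
#' @return G+C fraction over the selected positions.
#' @examples
#' codonPositionGC("ATGGCGTAA", "3")  # 2/3
#' @export
codonPositionGC <- function(cds, position = c("3", "1", "2", "12")) {
  position <- match.arg(as.character(position), c("3", "1", "2", "12"))
  s <- .normalizeSeq(cds, "cds")
  n <- nchar(s)
  if (n < 3L) stop("cds shorter than one codon")
  if (n %% 3L != 0L) {
    warning("trailing partial codon ignored (", n %% 3L, " nt)")
    n <- n - n %% 3L
  }
  ch <- .seqChars(substr(s, 1L, n))
  pos_in_codon <- rep(1:3, n / 3L)
  keep <- switch(position,
                 "1" = pos_in_codon == 1L,
                 "2" = pos_in_codon == 2L,
                 "3" = pos_in_codon == 3L,
                 "12" = pos_in_codon != 3L)
  ch <- ch[keep & ch != "N"]
  denom <- length(ch)
  if (denom == 0) stop("G+C content undefined at requested positions")
  sum(ch %in% c("G", "C")) / denom
}

#' Correlate UTR and CDS G+C content
#'
#' Pearson correlation with a two-sided p-value, an ordinary
#' least-squares regression line and a pointwise 95 percent confidence
#' band at the observed x values. Zero variance in either coordinate
#' leaves r undefined and is an error.
#'
#' @param utr_gc,cds_gc Paired numeric vectors (G+C fractions or
#'   percents) of equal length >= 3.
#' @return A \linkS4class{GcCorrelation}.
#' @examples
#' gcCorrelation(c(0.3, 0.5, 0.7), c(0.35, 0.52, 0.68))
#' @export
gcCorrelation <- function(utr_gc, cds_gc) {
  if (length(utr_gc) != length(cds_gc)) stop("pair vectors differ in length")
  keep <- is.finite(utr_gc) & is.finite(cds_gc)
  x <- utr_gc[keep]; y <- cds_gc[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one coordinate: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- lm(y ~ x)
  pr <- predict(fit, newdata = data.frame(x = x), interval = "confidence",
                level = 0.95)
  new("GcCorrelation",
      r = unname(ct$estimate), pValue = ct$p.value,
      slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
      n = length(x),
      band = data.frame(x = x, fit = pr[, "fit"], lwr = pr[, "lwr"],
                        upr = pr[, "upr"]))
}

#' @importFrom stats coef sd
NULL
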