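#' Find upstream AUG codons in a 5' UTR
#'
#' All occurrences of ATG in any frame, overlapping allowed, in
#' ascending order.
#'
#' @param utr5 5' UTR sequence (character scalar, DNA alphabet; U is
#'   mapped to T).
#' @return Integer vector of 1-based positions of the A of each AUG.
#' @examples
#' findUaugs("CCATGCCATGCC")  # 3, 8
#' @export
findUaugs <- function(utr5) {
  s <- .normalizeSeq(utr5, "utr5")
  .motifHits(s, "ATG")
}

#' Extract upstream open reading frames
#'
#' Each uAUG is followed in its own frame to the first in-frame stop
#' codon (TAA/TAG/TGA) inside the UTR. With
#' \code{requireStopInUtr = TRUE} (the default) only stop-containing
#' uORFs are reported; otherwise ORFs that run off the UTR 3' end into
#' the CDS are also emitted, flagged as overlapping, with
#' \code{stop_end = NA}. Context and cap-distance classes are filled in
#' via \code{\link{classifyUorfs}}.
#'
#' @param utr5 5' UTR sequence.
#' @param minCodons Minimum peptide length in codons, start codon
#'   included, stop excluded (default 1 = start + stop).
#' @param requireStopInUtr Drop ORFs without an in-frame stop in the
#'   UTR (default TRUE).
#' @return A \code{DataFrame} with one row per uORF: \code{start},
#'   \code{stop_end}, \code{cap_distance}, \code{peptide_length},
#'   \code{overlaps_cds}, \code{context_minus3}, \code{context_plus4},
#'   \code{context_class}, \code{distance_class}.
#' @examples
#' extractUorfs("AAATGAAATAGCC")  # one uORF, start 3, stop_end 11
#' @export
extractUorfs <- function(utr5, minCodons = 1L, requireStopInUtr = TRUE) {
  if (minCodons < 1L) stop("minCodons must be >= 1")
  s <- .normalizeSeq(utr5, "utr5")
  n <- nchar(s)
  starts <- .motifHits(s, "ATG")
  rows <- lapply(starts, function(st) {
    stop_end <- NA_integer_
    p <- st + 3L
    while (p + 2L <= n) {
      codon <- substr(s, p, p + 2L)
      if (codon %in% STOP_CODONS) { stop_end <- p + 2L; break }
      p <- p + 3L
    }
    overlaps <- is.na(stop_end)
    if (overlaps && requireStopInUtr) return(NULL)
    pep <- if (overlaps) (n - st + 1L) %/% 3L else (stop_end - st + 1L) %/% 3L - 1L
    if (pep < minCodons) return(NULL)
    data.frame(start = st, stop_end = stop_end, cap_distance = st - 1L,
               peptide_length = pep, overlaps_cds = overlaps)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), stop_end = integer(0),
               cap_distance = integer(0), peptide_length = integer(0),
               overlaps_cds = logical(0))
  classifyUorfs(S4Vectors::DataFrame(out), s)
}

#' Classify uORF initiation context and cap distance
#'
#' Context follows the Kozak-style rule on the bases at -3 and +4
#' around the AUG: \code{optimal} when the -3 base is A or G and the +4
#' base is G, \code{adequate} when exactly one of the two holds, and
#' \code{weak} otherwise; a missing -3 position (cap distance < 3)
#' counts as not satisfying the -3 condition. The cap-distance class is
#' \code{optimal} above 19 nt, \code{weak} below 12 nt, and
#' \code{intermediate} in the 12-19 nt band that the two published
#' categories leave undefined.
#'
#' @param uorfs A \code{DataFrame}/data.frame with at least a
#'   \code{start} column (1-based A of the AUG).
#' @param utr5 The 5' UTR sequence the coordinates refer to.
#' @return \code{uorfs} with \code{context_minus3}, \code{context_plus4},
#'   \code{context_class}, \code{distance_class} columns filled.
#' @export
classifyUorfs <- function(uorfs, utr5) {
  s <- .normalizeSeq(utr5, "utr5")
  n <- nchar(s)
  uorfs <- S4Vectors::DataFrame(uorfs)
  st <- uorfs$start
  if (length(st) && (any(st < 1L) || any(st + 2L > n)))
    stop("uORF coordinates out of range")
  m3 <- ifelse(st >= 4L, substring(s, st - 3L, st - 3L), NA_character_)
  p4 <- ifelse(st + 3L <= n, substring(s, st + 3L, st + 3L), NA_character_)
  ok3 <- !is.na(m3) & m3 %in% c("A", "G")
  ok4 <- !is.na(p4) & p4 == "G"
  ctx <- ifelse(ok3 & ok4, "optimal", ifelse(ok3 | ok4, "adequate", "weak"))
  cd <- st - 1L
  dist <- ifelse(cd > 19L, "optimal", ifelse(cd < 12L, "weak", "intermediate"))
  uorfs$context_minus3 <- as.character(m3)
  uorfs$context_plus4 <- as.character(p4)
  uorfs$context_class <- as.character(ctx)
  uorfs$distance_class <- as.character(dist)
  uorfs
}

#' Summarise the translation-relevant features of a 5' UTR
#'
#' @param utr5 5' UTR sequence.
#' @param minCodons,requireStopInUtr Passed to
#'   \code{\link{extractUorfs}}.
#' @param mfePerNt Optional folding energy per nucleotide (kcal/mol/nt)
#'   used by the translation-class rule.
#' @param thresholds See \code{\link{cartThresholds}}.
#' @return A list with \code{n_uaug}, \code{n_uorf}, \code{uorfs}
#'   (DataFrame), \code{length}, \code{gc_percent},
#'   \code{efficiency_string}, \code{context_string} (O/W summary
#'   strings such as \code{"O2/W1"}), and \code{cart_class}.
#' @export
translationProfile <- function(utr5, minCodons = 1L, requireStopInUtr = TRUE,
                               mfePerNt = NA_real_,
                               thresholds = cartThresholds()) {
  s <- .normalizeSeq(utr5, "utr5")
  uaugs <- findUaugs(s)
  uorfs <- extractUorfs(s, minCodons = minCodons,
                        requireStopInUtr = requireStopInUtr)
  comp <- gcContent(s)
  list(n_uaug = length(uaugs), n_uorf = nrow(uorfs), uorfs = uorfs,
       length = nchar(s), gc_percent = comp$gc_percent[1L],
       efficiency_string = .owString(uorfs$distance_class),
       context_string = .owString(uorfs$context_class),
       cart_class = assignTranslationClass(nrow(uorfs), nchar(s),
                                           mfePerNt = mfePerNt,
                                           thresholds = thresholds))
}

## collapse class labels to the published two-letter O/W summary:
## optimal/adequate/intermediate -> O, weak -> W; e.g. "O2/W1"
.owString <- function(classes) {
  if (!length(classes)) return("")
  o <- sum(classes != "weak")
  w <- sum(classes == "weak")
  paste(c(if (o) paste0("O", o), if (w) paste0("W", w)), collapse = "/")
}

#' Thresholds for the translation-efficiency surrogate rule
#'
#' Defaults: 5' UTRs no longer than 100 nt, with no uORF, and (when a
#' folding energy is supplied) at least -0.45 kcal/mol/nt are called
#' efficiently translated (class III); everything else class I. This is
#' an explicit surrogate for a published classification-and-regression
#' tree whose internals are not reproduced here; the thresholds are
#' configuration, not a fitted model.
#'
#' @param maxLengthNt Maximum 5' UTR length for class III.
#' @param minMfePerNt Minimum folding energy per nucleotide for class
#'   III (kcal/mol/nt; less negative = less structured).
#' @return A list of thresholds.
#' @export
cartThresholds <- function(maxLengthNt = 100, minMfePerNt = -0.45) {
  list(maxLengthNt = maxLengthNt, minMfePerNt = minMfePerNt)
}

#' Assign the translation-efficiency class (I or III)
#'
#' @param nUorf Number of uORFs.
#' @param lengthNt 5' UTR length in nucleotides.
#' @param gcPercent Unused by the default rule; accepted so callers can
#'   pass a full feature row.
#' @param mfePerNt Optional folding energy per nucleotide.
#' @param thresholds See \code{\link{cartThresholds}}.
#' @return \code{"I"} (low translation) or \code{"III"} (efficient).
#' @examples
#' assignTranslationClass(0, 54)   # "III"
#' assignTranslationClass(1, 232)  # "I"
#' @export
assignTranslationClass <- function(nUorf, lengthNt, gcPercent = NA_real_,
                                   mfePerNt = NA_real_,
                                   thresholds = cartThresholds()) {
  ok <- nUorf == 0 & lengthNt <= thresholds$maxLengthNt &
    (is.na(mfePerNt) | mfePerNt >= thresholds$minMfePerNt)
  ifelse(ok, "III", "I")
}

#' Histogram of uORF cap distances
#'
#' @param x Numeric vector of cap distances, or a list of profiles from
#'   \code{\link{translationProfile}} (their uORFs are pooled).
#' @param binWidth Bin width in nucleotides (>= 1); bins are
#'   \code{[0, binWidth)}, \code{[binWidth, 2 binWidth)}, ...
#' @return A data.frame with \code{bin_start}, \code{bin_end},
#'   \code{count}; counts sum to the number of uORFs.
#' @export
capDistanceHistogram <- function(x, binWidth = 10L) {
  if (binWidth < 1L) stop("binWidth must be >= 1")
  if (is.list(x) && !is.data.frame(x))
    x <- unlist(lapply(x, function(p) p$uorfs$cap_distance))
  x <- as.numeric(x)
  nbin <- if (length(x)) max(floor(x / binWidth)) + 1L else 1L
  idx <- if (length(x)) floor(x / binWidth) + 1L else integer(0)
  counts <- tabulate(idx, nbins = nbin)
  data.frame(bin_start = (seq_len(nbin) - 1L) * binWidth,
             bin_end = seq_len(nbin) * binWidth,
             count = counts)
}
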