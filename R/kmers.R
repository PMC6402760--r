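#' Count k-mer occurrences across a sequence set
#'
#' Overlapping occurrences are counted across all sequences. In
#' two-strand mode a word's count is merged with its reverse
#' complement's occurrences and the result is keyed by the
#' lexicographically smaller word of the pair (reverse-complement
#' palindromes are counted once).
#'
#' @param sequences Character vector, \code{DNAStringSet} or
#'   \linkS4class{UtrCatalog}.
#' @param k Word length, 4 to 10.
#' @param twoStrand Merge reverse-complement pairs (default TRUE).
#' @return Named integer vector of counts (words never observed are
#'   omitted).
#' @examples
#' countKmers("AAAA", k = 4, twoStrand = FALSE)
#' @export
countKmers <- function(sequences, k, twoStrand = TRUE) {
  if (k < 4L || k > 10L) stop("k must be between 4 and 10")
  seqs <- .asSeqChar(sequences)
  if (all(nchar(seqs) < k)) stop("k is longer than every sequence")
  sset <- Biostrings::DNAStringSet(seqs[nchar(seqs) >= k])
  counts <- colSums(Biostrings::oligonucleotideFrequency(sset, width = k))
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  if (!twoStrand) return(counts)
  words <- names(counts)
  rcs <- vapply(words, .revcomp, character(1))
  keys <- pmin(words, rcs)
  merged <- tapply(counts, keys, sum)
  out <- as.integer(merged)
  names(out) <- names(merged)
  ## a palindrome's forward occurrences were counted once; keep as is
  out[order(names(out))]
}

.asSeqChar <- function(x) {
  if (is(x, "UtrCatalog")) x <- catalogSequences(x)
  if (is(x, "DNAStringSet")) x <- as.character(x)
  unname(vapply(x, .normalizeSeq, character(1)))
}

#' Estimate a Markov background model from sequences
#'
#' Order-m transition probabilities (m in 0, 1, 2) estimated from
#' overlapping (m+1)-mer counts with a pseudo-count added to every
#' cell, so no word needed later can have probability exactly zero
#' unless \code{pseudocount = 0}.
#'
#' @param sequences Sequence set (character, \code{DNAStringSet} or
#'   catalog).
#' @param order Markov order, 0, 1 or 2.
#' @param pseudocount Added to every (m+1)-mer count (default 0.01).
#' @return An object of class \code{MarkovBackground}: a list with
#'   \code{order}, \code{prefix} (probabilities of the 4^m order-m
#'   words) and \code{trans} (4^m x 4 transition matrix).
#' @export
markovBackground <- function(sequences, order = 2L, pseudocount = 0.01) {
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  seqs <- .asSeqChar(sequences)
  sset <- Biostrings::DNAStringSet(seqs)
  m <- as.integer(order)
  ctx <- colSums(Biostrings::oligonucleotideFrequency(sset, width = m + 1L)) +
    pseudocount
  words <- names(ctx)
  if (m == 0L) {
    prefix <- setNames(1, "")
    trans <- matrix(ctx / sum(ctx), nrow = 1,
                    dimnames = list("", words))
  } else {
    pre <- substr(words, 1L, m)
    nxt <- substr(words, m + 1L, m + 1L)
    trans <- tapply(ctx, list(pre, nxt), sum)
    trans <- trans / rowSums(trans)
    pw <- colSums(Biostrings::oligonucleotideFrequency(sset, width = m)) +
      pseudocount
    prefix <- pw / sum(pw)
  }
  structure(list(order = m, prefix = prefix, trans = trans,
                 pseudocount = pseudocount),
            class = "MarkovBackground")
}

#' Probability of a word under a Markov background
#'
#' @param kmer Word (DNA alphabet).
#' @param background A \code{\link{markovBackground}} model.
#' @return Probability of observing \code{kmer} at a fixed position.
#' @export
kmerProbability <- function(kmer, background) {
  stopifnot(inherits(background, "MarkovBackground"))
  w <- .normalizeSeq(kmer, "kmer")
  m <- background$order
  if (nchar(w) <= m) stop("kmer shorter than the model order + 1")
  p <- if (m == 0L) 1 else background$prefix[[substr(w, 1L, m)]]
  if (is.null(p) || is.na(p)) p <- 0
  for (i in seq.int(m + 1L, nchar(w))) {
    step <- if (m == 0L) background$trans[1L, substr(w, i, i)]
            else background$trans[substr(w, i - m, i - 1L), substr(w, i, i)]
    if (is.na(step) || step == 0)
      stop("zero-probability transition for '", w,
           "'; use a positive pseudocount to smooth the background")
    p <- p * step
  }
  unname(p)
}

#' Expected count of a word under a background model
#'
#' @param kmer Word.
#' @param background A \code{\link{markovBackground}} model.
#' @param totalPositions Number of sliding-window positions scanned
#'   (one strand).
#' @param twoStrand Sum the probabilities of the word and its reverse
#'   complement (palindromes counted once), matching two-strand
#'   counting.
#' @return Expected occurrence count.
#' @export
expectedKmerCount <- function(kmer, background, totalPositions,
                              twoStrand = TRUE) {
  w <- .normalizeSeq(kmer, "kmer")
  p <- kmerProbability(w, background)
  if (twoStrand) {
    rc <- .revcomp(w)
    if (rc != w) p <- p + kmerProbability(rc, background)
  }
  totalPositions * p
}

#' Binomial significance of an observed k-mer count
#'
#' Upper-tail binomial probability of observing at least the observed
#' count in \code{totalPositions} trials with per-position probability
#' \code{expected / totalPositions}, Bonferroni-corrected over
#' \code{nTests} words into an E-value; the significance index is
#' -log10 of that E-value (positive = fewer than one such event
#' expected by chance).
#'
#' @param observed Observed count (>= 0).
#' @param expected Expected count (> 0).
#' @param nTests Number of words tested (>= 1).
#' @param totalPositions Number of scanned positions.
#' @return A data.frame with \code{p_value}, \code{e_value},
#'   \code{sig_index}.
#' @export
kmerSignificance <- function(observed, expected, nTests, totalPositions) {
  if (any(observed < 0)) stop("observed count must be >= 0")
  if (any(expected <= 0)) stop("expected count must be > 0")
  if (any(nTests < 1)) stop("nTests must be >= 1")
  p <- pbinom(observed - 1, size = totalPositions,
              prob = pmin(expected / totalPositions, 1), lower.tail = FALSE)
  e <- nTests * p
  data.frame(p_value = p, e_value = e, sig_index = -log10(e))
}

#' Detect over-represented oligonucleotides in a sequence set
#'
#' Counts words of length \code{k} (two-strand by default), estimates
#' expected counts under a Markov background trained on the input set
#' itself, and ranks words by significance index.
#'
#' @param sequences Sequence set.
#' @param k Word length (6-8 typical).
#' @param order Markov background order (default 2).
#' @param twoStrand Two-strand counting (default TRUE).
#' @param nTests Number of tests for the Bonferroni E-value; default
#'   the number of distinct observed words.
#' @param pseudocount Background smoothing (default 0.01).
#' @return A \code{DataFrame} sorted by decreasing \code{sig_index}
#'   with columns \code{kmer}, \code{observed}, \code{expected},
#'   \code{p_value}, \code{sig_index}.
#' @export
kmerEnrichment <- function(sequences, k = 6L, order = 2L, twoStrand = TRUE,
                           nTests = NULL, pseudocount = 0.01) {
  seqs <- .asSeqChar(sequences)
  counts <- countKmers(seqs, k = k, twoStrand = twoStrand)
  bg <- markovBackground(seqs, order = order, pseudocount = pseudocount)
  totalPositions <- sum(pmax(nchar(seqs) - k + 1L, 0L))
  if (is.null(nTests)) nTests <- length(counts)
  expected <- vapply(names(counts), expectedKmerCount, numeric(1),
                     background = bg, totalPositions = totalPositions,
                     twoStrand = twoStrand)
  sig <- kmerSignificance(as.integer(counts), expected, nTests,
                          totalPositions)
  out <- S4Vectors::DataFrame(kmer = names(counts),
                              observed = as.integer(counts),
                              expected = unname(expected),
                              p_value = sig$p_value,
                              sig_index = sig$sig_index)
  out[order(-out$sig_index, out$kmer), ]
}
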