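#' Global pairwise percent identity
#'
#' Needleman-Wunsch-style global alignment (match +1, mismatch -1, gap
#' open -10, gap extend -0.5 by default, via
#' \code{Biostrings::pairwiseAlignment}). Identity is the fraction of
#' matching columns over all alignment columns excluding terminal-gap
#' columns, so UTR variants that differ in length at their ends are
#' compared over their aligned core; internal gap columns count as
#' mismatches.
#'
#' @param a,b Nucleotide sequences (character scalars).
#' @param scoring List with \code{match}, \code{mismatch},
#'   \code{gapOpening}, \code{gapExtension} (positive penalties).
#' @return Percent identity in [0, 100].
#' @examples
#' pairwiseIdentity("ACGT", "ACGA")  # 75
#' @export
pairwiseIdentity <- function(a, b,
                             scoring = list(match = 1, mismatch = -1,
                                            gapOpening = 10,
                                            gapExtension = 0.5)) {
  sa <- .normalizeSeq(a, "a"); sb <- .normalizeSeq(b, "b")
  if (identical(sa, sb)) return(100)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
  .alignedIdentity(as.character(Biostrings::alignedPattern(pa)),
                   as.character(Biostrings::alignedSubject(pa)))
}

## identity over two aligned (equal-length, gapped) strings, excluding
## terminal-gap columns on either sequence
.alignedIdentity <- function(x, y) {
  cx <- .seqChars(x); cy <- .seqChars(y)
  n <- length(cx)
  gap <- cx == "-" | cy == "-"
  from <- 1L
  while (from <= n && gap[from]) from <- from + 1L
  to <- n
  while (to >= 1L && gap[to]) to <- to - 1L
  if (from > to) return(0)
  keep <- from:to
  ## drop columns where both sequences are gapped (possible in MSA mode)
  both <- cx[keep] == "-" & cy[keep] == "-"
  keep <- keep[!both]
  if (!length(keep)) return(0)
  100 * sum(cx[keep] == cy[keep] & cx[keep] != "-") / length(keep)
}

#' Identity partitioned by codon position
#'
#' For two aligned, in-frame coding sequences, identity is computed
#' separately over codon positions 1+2 and position 3. Alignment
#' codons (triplets of columns) containing a gap or N in either
#' sequence are excluded pairwise.
#'
#' @param cdsA,cdsB Aligned coding sequences of equal length divisible
#'   by 3 (gaps allowed as \code{"-"}).
#' @return Named numeric vector \code{c(id_pos12, id_pos3)} (percent).
#' @examples
#' codonPartitionIdentity("ATGGCGAAA", "ATGGCAAAG")
#' @export
codonPartitionIdentity <- function(cdsA, cdsB) {
  ca <- .seqChars(toupper(chartr("u", "U", chartr("U", "T", cdsA))))
  cb <- .seqChars(toupper(chartr("u", "U", chartr("U", "T", cdsB))))
  if (length(ca) != length(cb)) stop("aligned sequences differ in length")
  if (length(ca) %% 3L != 0L) stop("frame mismatch: length not divisible by 3")
  ncod <- length(ca) %/% 3L
  keep <- vapply(seq_len(ncod), function(c0) {
    idx <- (3L * (c0 - 1L) + 1L):(3L * c0)
    !any(ca[idx] %in% c("-", "N") | cb[idx] %in% c("-", "N"))
  }, logical(1))
  if (!any(keep)) stop("no gap-free codons to compare")
  idx <- unlist(lapply(which(keep), function(c0) (3L * (c0 - 1L) + 1L):(3L * c0)))
  posInCodon <- rep(1:3, sum(keep))
  same <- ca[idx] == cb[idx]
  c(id_pos12 = 100 * mean(same[posInCodon != 3L]),
    id_pos3 = 100 * mean(same[posInCodon == 3L]))
}

#' Pairwise identity matrix over a labeled sequence set
#'
#' @param sequences Named character vector or \code{DNAStringSet}
#'   (>= 2 sequences). In \code{msa_columns} mode the sequences must be
#'   pre-aligned (equal lengths, gaps as \code{"-"}).
#' @param mode \code{"pairwise_global"} (align each pair) or
#'   \code{"msa_columns"} (column-wise identity over a pre-built
#'   multiple alignment).
#' @param scoring Passed to \code{\link{pairwiseIdentity}}.
#' @return An \linkS4class{IdentityMatrix} with input label order
#'   preserved.
#' @export
distanceMatrix <- function(sequences,
                           mode = c("pairwise_global", "msa_columns"),
                           scoring = list(match = 1, mismatch = -1,
                                          gapOpening = 10,
                                          gapExtension = 0.5)) {
  mode <- match.arg(mode)
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  labels <- names(sequences)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  if (mode == "msa_columns" && length(unique(nchar(sequences))) != 1L)
    stop("msa_columns mode requires pre-aligned sequences of equal length")
  v <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v[i, j] <- v[j, i] <- if (mode == "pairwise_global")
        pairwiseIdentity(sequences[[i]], sequences[[j]], scoring = scoring)
      else
        .alignedIdentity(sequences[[i]], sequences[[j]])
    }
  }
  new("IdentityMatrix", values = v, method = mode)
}

#' Homology call from percent identity
#'
#' Inclusive threshold: identity at exactly the threshold is called
#' homologous.
#'
#' @param identity Percent identity in [0, 100].
#' @param threshold Percent threshold (default 60).
#' @return Logical.
#' @examples
#' homologyCall(78.2)  # TRUE
#' homologyCall(45.6)  # FALSE
#' @export
homologyCall <- function(identity, threshold = 60) {
  if (any(identity < 0 | identity > 100)) stop("identity must be in [0, 100]")
  identity >= threshold
}

## per-codon synonymous site fraction; mutations to stop codons count
## as nonsynonymous
.codonSynSites <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!code[[mut]] %in% "*" && code[[mut]] == aa) syn <- syn + 1
    }
  }
  syn / 3
}

## average syn/nonsyn substitution counts between two codons over all
## shortest mutational pathways; pathways through stop codons are
## discarded (all pathways are used if every one hits a stop)
.codonPathCounts <- function(c1, c2, code) {
  diffpos <- which(.seqChars(c1) != .seqChars(c2))
  d <- length(diffpos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- .permutations(diffpos)
  tally <- function(throughStopsAllowed) {
    res <- matrix(NA_real_, length(perms), 2)
    for (pi in seq_along(perms)) {
      cur <- c1
      sd <- 0; nd <- 0; ok <- TRUE
      for (pos in perms[[pi]]) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (code[[nxt]] == "*" && !throughStopsAllowed) { ok <- FALSE; break }
        if (code[[cur]] != "*" && code[[nxt]] != "*" &&
            code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res[pi, ] <- c(sd, nd)
    }
    res[!is.na(res[, 1L]), , drop = FALSE]
  }
  res <- tally(FALSE)
  if (!nrow(res)) res <- tally(TRUE)
  c(sd = mean(res[, 1L]), nd = mean(res[, 2L]))
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Nei-Gojobori (1986) Ka/Ks between two aligned coding sequences
#'
#' Synonymous and nonsynonymous site counts are computed per codon as
#' the fraction of single-nucleotide changes that preserve the amino
#' acid (changes to stop codons count as nonsynonymous) and averaged
#' over the two sequences. Substitutions between differing codons are
#' averaged over all shortest mutational pathways, discarding pathways
#' that pass through a stop codon when an alternative exists. The
#' proportions pN and pS are corrected for multiple hits with the
#' Jukes-Cantor formula d = -3/4 log(1 - 4p/3); a proportion >= 3/4
#' leaves the corrected rate undefined (NA, flagged) rather than an
#' error. Codons containing gaps or Ns, and codon pairs where either
#' codon is a stop, are excluded.
#'
#' @param cdsA,cdsB Aligned, in-frame coding sequences of equal length.
#' @return A list with \code{ka}, \code{ks}, \code{ratio} (NA when ks
#'   is 0 or either rate is undefined), \code{n_sites}, \code{s_sites},
#'   \code{nd}, \code{sd}, \code{codons} (number compared) and
#'   \code{undefined} (flag).
#' @examples
#' kaksNG86("GTTGTTGTT", "GTAGTTGTT")  # ks ~ 0.4408, ka 0
#' @export
kaksNG86 <- function(cdsA, cdsB) {
  sa <- toupper(chartr("U", "T", cdsA))
  sb <- toupper(chartr("U", "T", cdsB))
  if (nchar(sa) != nchar(sb)) stop("aligned sequences differ in length")
  if (nchar(sa) %% 3L != 0L) stop("frame mismatch: length not divisible by 3")
  code <- as.list(Biostrings::GENETIC_CODE)
  ncod <- nchar(sa) %/% 3L
  sA <- sB <- 0; sd <- nd <- 0; used <- 0L
  for (c0 in seq_len(ncod)) {
    i <- 3L * (c0 - 1L) + 1L
    ca <- substr(sa, i, i + 2L); cb <- substr(sb, i, i + 2L)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (code[[ca]] == "*" || code[[cb]] == "*") next
    used <- used + 1L
    sA <- sA + .codonSynSites(ca, code)
    sB <- sB + .codonSynSites(cb, code)
    cnt <- .codonPathCounts(ca, cb, code)
    sd <- sd + cnt[["sd"]]; nd <- nd + cnt[["nd"]]
  }
  if (used == 0L) stop("no comparable codons")
  s_sites <- (sA + sB) / 2
  n_sites <- 3 * used - s_sites
  pS <- if (s_sites > 0) sd / s_sites else 0
  pN <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(pS); ka <- jc(pN)
  undefined <- is.na(ks) || is.na(ka) || (!is.na(ks) && ks == 0)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, ratio = ratio, n_sites = n_sites,
       s_sites = s_sites, nd = unname(nd), sd = unname(sd),
       codons = used, undefined = undefined)
}
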