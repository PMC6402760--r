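#' Find seed-complementary candidate miRNA sites in a 3' UTR
#'
#' The miRNA seed (positions 1..\code{minSeed} from its 5' end) is
#' paired antiparallel against every UTR window: seed position i pairs
#' with the window base \code{minSeed - i + 1} from the window's 3'
#' end. Watson-Crick pairs and up to \code{maxGU} G:U wobbles plus
#' \code{maxMismatch} mismatches are allowed, except at seed position
#' 1, which must be a Watson-Crick pair.
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param utr3 3' UTR sequence.
#' @param minSeed Minimum seed length, >= 6 (default 8).
#' @param maxGU Maximum G:U wobbles in the seed (default 1).
#' @param maxMismatch Maximum mismatches in the seed (default 1).
#' @return A \code{DataFrame} with \code{site_start}, \code{site_end}
#'   (1-based UTR coordinates of the seed-paired region),
#'   \code{seed_len}, \code{n_gu}, \code{n_mismatch}, ascending by
#'   \code{site_start}.
#' @examples
#' findSeedMatches("TGAGGTAGTAGGTTGTATAGTT", "GGGCTACCTCAGGG")
#' @export
findSeedMatches <- function(mirna, utr3, minSeed = 8L, maxGU = 1L,
                            maxMismatch = 1L) {
  if (minSeed < 6L) stop("minSeed must be >= 6")
  m <- .normalizeSeq(mirna, "mirna")
  s <- .normalizeSeq(utr3, "utr3")
  if (nchar(m) < minSeed) stop("miRNA shorter than the seed")
  seed <- .seqChars(substr(m, 1L, minSeed))
  utr <- .seqChars(s)
  n <- nchar(s)
  rows <- list()
  for (p in seq_len(max(n - minSeed + 1L, 0L))) {
    ngu <- 0L; nmm <- 0L; ok <- TRUE
    for (i in seq_len(minSeed)) {
      a <- seed[i]
      b <- utr[p + minSeed - i]          # antiparallel partner
      wc <- (a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")
      gu <- (a == "G" && b == "T") || (a == "T" && b == "G")
      if (wc) next
      if (i == 1L) { ok <- FALSE; break }  # position 1 must be WC
      if (gu) ngu <- ngu + 1L else nmm <- nmm + 1L
      if (ngu > maxGU || nmm > maxMismatch) { ok <- FALSE; break }
    }
    if (ok)
      rows[[length(rows) + 1L]] <-
        data.frame(site_start = p, site_end = p + minSeed - 1L,
                   seed_len = minSeed, n_gu = ngu, n_mismatch = nmm)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_start = integer(0), site_end = integer(0),
               seed_len = integer(0), n_gu = integer(0),
               n_mismatch = integer(0))
  S4Vectors::DataFrame(out)
}

#' Score a candidate site's accessibility
#'
#' The opening energy dGopen is the ensemble energy of the
#' unconstrained fold of a window around the site minus the ensemble
#' energy with the site forced unpaired (a constrained, hence
#' higher-or-equal, energy), so dGopen <= 0 by construction. The
#' accessibility score is ddG = dGduplex - dGopen. Sites with
#' ddG < \code{ddgThreshold} are accessible; among those, sites whose
#' opening cost is small (dGopen > \code{dgOpenThreshold}) are very
#' accessible.
#'
#' @param sites Candidate sites from \code{\link{findSeedMatches}}.
#' @param utr3 The UTR sequence.
#' @param mirna The miRNA sequence (5' to 3').
#' @param engine A thermodynamic engine contract: a list with
#'   \code{duplexEnergy(mirna, target)} and
#'   \code{ensembleEnergy(seq, unpaired = NULL)} where \code{unpaired}
#'   is a \code{c(start, end)} range (1-based, within \code{seq})
#'   forced single-stranded. See \code{\link{stubEnergyEngine}},
#'   \code{\link{toyEnergyEngine}}, \code{\link{viennaEnergyEngine}}.
#' @param flank Nucleotides of UTR context on each side of the site
#'   used for the opening-energy window (default 70, truncated at the
#'   UTR ends).
#' @param ddgThreshold,dgOpenThreshold Classification thresholds in
#'   kcal/mol (defaults -10 and -10).
#' @return \code{sites} with \code{dg_duplex}, \code{dg_open},
#'   \code{ddg} and \code{access_class} columns added.
#' @export
scoreSites <- function(sites, utr3, mirna, engine, flank = 70L,
                       ddgThreshold = -10, dgOpenThreshold = -10) {
  s <- .normalizeSeq(utr3, "utr3")
  m <- .normalizeSeq(mirna, "mirna")
  sites <- S4Vectors::DataFrame(sites)
  n <- nchar(s)
  dgd <- dgo <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    st <- sites$site_start[i]; en <- sites$site_end[i]
    ## full-length miRNA pairs the region ending at the seed's 3'-most
    ## UTR base (antiparallel): target window [en - len(m) + 1, en]
    tgt <- substr(s, max(1L, en - nchar(m) + 1L), en)
    wst <- max(1L, st - flank); wen <- min(n, en + flank)
    win <- substr(s, wst, wen)
    e_un <- engine$ensembleEnergy(win)
    e_con <- engine$ensembleEnergy(win, unpaired = c(st - wst + 1L,
                                                     en - wst + 1L))
    dgd[i] <- engine$duplexEnergy(m, tgt)
    dgo[i] <- e_un - e_con
  }
  sites$dg_duplex <- dgd
  sites$dg_open <- dgo
  sites$ddg <- dgd - dgo
  sites$access_class <- ifelse(sites$ddg >= ddgThreshold, "inaccessible",
                               ifelse(sites$dg_open > dgOpenThreshold,
                                      "very_accessible", "accessible"))
  sites
}

#' Count accessible and very accessible sites
#'
#' Very accessible sites are a subset of accessible sites, so
#' \code{n_very_accessible <= n_accessible} always.
#'
#' @param sites Scored sites from \code{\link{scoreSites}}.
#' @return Named integer vector \code{c(n_accessible, n_very_accessible)}.
#' @export
classifyTargets <- function(sites) {
  sites <- as.data.frame(sites)
  acc <- sum(sites$access_class %in% c("accessible", "very_accessible"))
  very <- sum(sites$access_class == "very_accessible")
  c(n_accessible = as.integer(acc), n_very_accessible = as.integer(very))
}

#' Deterministic stub thermodynamic engine
#'
#' Returns fixed duplex and opening energies regardless of sequence;
#' used to test the ddG arithmetic and classification thresholds in
#' isolation from any folding model.
#'
#' @param dgDuplex Duplex energy to report (kcal/mol).
#' @param dgOpen Opening energy to report (kcal/mol, <= 0).
#' @return An engine contract list.
#' @examples
#' eng <- stubEnergyEngine(-22, -5)
#' eng$duplexEnergy("ACGT", "ACGT")
#' @export
stubEnergyEngine <- function(dgDuplex, dgOpen) {
  if (dgOpen > 0) stop("dgOpen must be <= 0")
  list(
    duplexEnergy = function(mirna, target) dgDuplex,
    ensembleEnergy = function(seq, unpaired = NULL)
      if (is.null(unpaired)) 0 else -dgOpen)
}

## toy pair energies (kcal/mol-like units): GC -3, AT -2, GT wobble -1
.toyPairEnergy <- function(a, b) {
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
  if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(-2)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(-1)
  0
}

#' Toy nearest-neighbour-free thermodynamic engine
#'
#' A deterministic, self-contained energy model: duplex energy is the
#' sum of simple pair energies (GC -3, AU -2, G:U -1 kcal/mol) over the
#' antiparallel alignment of the miRNA with the target, and ensemble
#' energy is the minimum base-pairing energy of the window under the
#' same pair energies with a minimum hairpin loop of 3 nt (computed by
#' dynamic programming, positions inside a constraint range excluded
#' from pairing). Intended for tests and small examples, not for
#' quantitative thermodynamics.
#'
#' @return An engine contract list.
#' @export
toyEnergyEngine <- function() {
  list(
    duplexEnergy = function(mirna, target) {
      a <- .seqChars(.normalizeSeq(mirna, "mirna"))
      b <- .seqChars(.normalizeSeq(target, "target"))
      k <- min(length(a), length(b))
      e <- 0
      for (i in seq_len(k))
        e <- e + .toyPairEnergy(a[i], b[length(b) - i + 1L])
      e
    },
    ensembleEnergy = function(seq, unpaired = NULL) {
      .nussinovMinEnergy(.normalizeSeq(seq, "window"), unpaired = unpaired)
    })
}

## minimum pairing energy, Nussinov-style DP, min loop 3; 'unpaired' is
## an inclusive range of positions barred from pairing
.nussinovMinEnergy <- function(seq, unpaired = NULL) {
  ch <- .seqChars(seq)
  n <- length(ch)
  allow <- rep(TRUE, n)
  if (!is.null(unpaired)) allow[unpaired[1L]:unpaired[2L]] <- FALSE
  pairE <- function(i, j) {
    if (!allow[i] || !allow[j]) return(NA_real_)
    e <- .toyPairEnergy(ch[i], ch[j])
    if (e == 0) NA_real_ else e
  }
  E <- matrix(0, n, n)
  if (n < 5L) return(0)
  for (span in 4:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- E[i + 1L, j]
      for (k in (i + 4L):j) {
        pe <- pairE(i, k)
        if (is.na(pe)) next
        inner <- if (k - i >= 5L) E[i + 1L, k - 1L] else 0
        outer <- if (k < j) E[k + 1L, j] else 0
        cand <- pe + inner + outer
        if (cand < best) best <- cand
      }
      E[i, j] <- best
    }
  }
  E[1L, n]
}

#' ViennaRNA-backed thermodynamic engine
#'
#' Wraps the RNAduplex and RNAfold command-line tools (partition
#' function ensemble free energies; constraints applied with the
#' RNAfold constraint syntax) when they are available on the PATH.
#'
#' @return An engine contract list, or an error if the tools are not
#'   found.
#' @export
viennaEnergyEngine <- function() {
  if (!nzchar(Sys.which("RNAduplex")) || !nzchar(Sys.which("RNAfold")))
    stop("RNAduplex/RNAfold not found on PATH")
  list(
    duplexEnergy = function(mirna, target) {
      out <- system2("RNAduplex", input = c(chartr("T", "U", mirna),
                                            chartr("T", "U", target)),
                     stdout = TRUE, stderr = FALSE)
      m <- regmatches(out[1L], regexpr("\\(\\s*-?[0-9.]+\\s*\\)", out[1L]))
      as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
    },
    ensembleEnergy = function(seq, unpaired = NULL) {
      rna <- chartr("T", "U", seq)
      if (is.null(unpaired)) {
        out <- system2("RNAfold", args = c("-p0", "--noPS"), input = rna,
                       stdout = TRUE, stderr = FALSE)
      } else {
        cons <- rep(".", nchar(seq))
        cons[unpaired[1L]:unpaired[2L]] <- "x"
        out <- system2("RNAfold", args = c("-p0", "--noPS", "-C"),
                       input = c(rna, paste(cons, collapse = "")),
                       stdout = TRUE, stderr = FALSE)
      }
      line <- grep("free energy of ensemble", out, value = TRUE)[1L]
      as.numeric(regmatches(line, regexpr("-?[0-9.]+", line)))
    })
}
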