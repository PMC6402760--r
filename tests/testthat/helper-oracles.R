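## Independent oracles used by the tests. These deliberately avoid the
## package's own code paths: naive loops, exhaustive enumeration and a
## hard-coded codon table.

## --- genetic code (hard-coded, independent of Biostrings) -----------
.oracleCodonTable <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTN, TCN, TAN, TGN
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- unlist(lapply(bases, function(b1)
    lapply(bases, function(b2) paste0(b1, b2, bases))))
  stats::setNames(aas, codons)
})

oracleTranslate <- function(codon) unname(.oracleCodonTable[codon])

## exhaustive-pathway NG86: site counts by enumerating all nine single
## changes per codon, substitution counts by DFS over orderings
oracleKaKs <- function(a, b) {
  ncod <- nchar(a) / 3
  bases <- c("A", "C", "G", "T")
  synSites <- function(codon) {
    aa <- oracleTranslate(codon)
    n <- 0
    for (pos in 1:3) for (bb in bases) {
      if (bb == substr(codon, pos, pos)) next
      mut <- paste0(substr(codon, 1, pos - 1), bb, substr(codon, pos + 1, 3))
      if (oracleTranslate(mut) != "*" && oracleTranslate(mut) == aa)
        n <- n + 1
    }
    n / 3
  }
  pathCounts <- function(c1, c2) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) return(c(0, 0))
    walk <- function(cur, remaining, allowStops) {
      if (!length(remaining)) return(list(c(0, 0)))
      out <- list()
      for (idx in seq_along(remaining)) {
        pos <- remaining[idx]
        nxt <- paste0(substr(cur, 1, pos - 1), substr(c2, pos, pos),
                      substr(cur, pos + 1, 3))
        if (oracleTranslate(nxt) == "*" && !allowStops) next
        step <- if (oracleTranslate(cur) != "*" &&
                    oracleTranslate(nxt) != "*" &&
                    oracleTranslate(cur) == oracleTranslate(nxt))
          c(1, 0) else c(0, 1)
        for (tail in walk(nxt, remaining[-idx], allowStops))
          out[[length(out) + 1]] <- step + tail
      }
      out
    }
    paths <- walk(c1, dp, FALSE)
    if (!length(paths)) paths <- walk(c1, dp, TRUE)
    m <- do.call(rbind, paths)
    colMeans(m)
  }
  sA <- sB <- 0; sd <- nd <- 0; used <- 0
  for (ci in seq_len(ncod)) {
    c1 <- substr(a, 3 * ci - 2, 3 * ci)
    c2 <- substr(b, 3 * ci - 2, 3 * ci)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (oracleTranslate(c1) == "*" || oracleTranslate(c2) == "*") next
    used <- used + 1
    sA <- sA + synSites(c1); sB <- sB + synSites(c2)
    pc <- pathCounts(c1, c2)
    sd <- sd + pc[1]; nd <- nd + pc[2]
  }
  s_sites <- (sA + sB) / 2
  n_sites <- 3 * used - s_sites
  pS <- if (s_sites > 0) sd / s_sites else 0
  pN <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(pN), ks = jc(pS), n_sites = n_sites, s_sites = s_sites,
       nd = nd, sd = sd)
}

## --- exhaustive secondary-structure enumeration ---------------------
## all pair sets over a sequence (canonical + GU, min loop 3), returned
## as dot-bracket strings; no DP, no pruning
oraclePairOK <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

oracleAllStructures <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  rec <- function(lo, hi) {
    if (lo >= hi) return(list(integer(0)))
    out <- rec(lo + 1, hi)                       # lo unpaired
    out <- lapply(out, identity)
    ks <- if (lo + 4 <= hi) (lo + 4):hi else integer(0)
    for (k in ks) {
      if (!oraclePairOK(ch[lo], ch[k])) next
      for (inn in rec(lo + 1, k - 1))
        for (outr in rec(k + 1, hi))
          out[[length(out) + 1]] <- c(lo, k, inn, outr)
    }
    out
  }
  structs <- rec(1, n)
  vapply(structs, function(pr) {
    db <- rep(".", n)
    if (length(pr)) {
      op <- pr[seq(1, length(pr), 2)]
      cl <- pr[seq(2, length(pr), 2)]
      db[op] <- "("; db[cl] <- ")"
    }
    paste(db, collapse = "")
  }, character(1))
}

## shape abstraction by graph reduction (independent of the package's
## tree recursion): repeatedly delete every pair that encloses exactly
## one directly-nested pair, then print the survivors
oracleShape <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0); pairs <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (is.null(pairs)) return("_")
  repeat {
    nchild <- vapply(seq_len(nrow(pairs)), function(p) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      inside <- pairs[, 1] > i & pairs[, 2] < j
      if (!any(inside)) return(0L)
      ## direct children: inside pairs not nested in another inside pair
      sum(vapply(which(inside), function(q) {
        !any(inside & pairs[, 1] < pairs[q, 1] & pairs[, 2] > pairs[q, 2])
      }, logical(1)))
    }, integer(1))
    drop <- which(nchild == 1L)
    if (!length(drop)) break
    pairs <- pairs[-drop[1], , drop = FALSE]
  }
  out <- rep("", length(ch))
  out[pairs[, 1]] <- "["
  out[pairs[, 2]] <- "]"
  paste(out, collapse = "")
}

## --- misc ------------------------------------------------------------
oracleKmerCount <- function(seqs, k) {
  counts <- list()
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in 1:(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      counts[[w]] <- (counts[[w]] %||% 0L) + 1L
    }
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracleRevcomp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

oracleMotifCount <- function(seq, motif) {
  n <- 0L
  if (nchar(seq) < nchar(motif)) return(0L)
  for (i in 1:(nchar(seq) - nchar(motif) + 1))
    if (substr(seq, i, i + nchar(motif) - 1) == motif) n <- n + 1L
  n
}

## expected pairwise identity of two leaves independently diverged from
## a common root with per-site substitution probability r
oracleLeafIdentity <- function(r) (1 - r)^2 + r^2 / 3

randomSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
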