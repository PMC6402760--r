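## pairing rule shared by the toy folding engine: canonical + G:U wobble
.canPairBases <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
}

## Nussinov table of minimum toy energies (-1 per pair, min loop 3)
.toyEnergyTable <- function(ch) {
  n <- length(ch)
  E <- matrix(0, n, n)
  if (n >= 5L) {
    for (span in 4:(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- E[i + 1L, j]
        for (k in (i + 4L):j) {
          if (!.canPairBases(ch[i], ch[k])) next
          cand <- -1 + E[i + 1L, k - 1L] + (if (k < j) E[k + 1L, j] else 0)
          if (cand < best) best <- cand
        }
        E[i, j] <- best
      }
    }
  }
  E
}

## Wuchty-style enumeration of all structures of [i, j] with energy <=
## maxE, using the DP table for pruning. Returns a list of integer
## pair matrices (2 columns: i, j).
.enumerateInterval <- function(ch, E, i, j, maxE) {
  if (i >= j || j - i < 4L) {
    return(if (0 <= maxE + 1e-9) list(cbind(integer(0), integer(0))) else list())
  }
  out <- list()
  ## case: i unpaired
  if (E[i + 1L, j] <= maxE + 1e-9)
    out <- c(out, .enumerateInterval(ch, E, i + 1L, j, maxE))
  ## case: i pairs k
  for (k in (i + 4L):j) {
    if (!.canPairBases(ch[i], ch[k])) next
    innerMin <- E[i + 1L, k - 1L]
    outerMin <- if (k < j) E[k + 1L, j] else 0
    if (-1 + innerMin + outerMin > maxE + 1e-9) next
    inners <- .enumerateInterval(ch, E, i + 1L, k - 1L,
                                 maxE + 1 - outerMin)
    for (inner in inners) {
      eInner <- -nrow(inner)
      outers <- if (k < j)
        .enumerateInterval(ch, E, k + 1L, j, maxE + 1 - eInner)
      else list(cbind(integer(0), integer(0)))
      for (outer in outers)
        out[[length(out) + 1L]] <- rbind(cbind(i, k), inner, outer)
    }
  }
  out
}

.pairsToDotBracket <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  paste(db, collapse = "")
}

#' Fold a sequence and enumerate suboptimal structures
#'
#' With the bundled toy engine, energies are -1 kcal/mol per base pair
#' (canonical plus G:U), the minimum hairpin loop is 3 nt, and every
#' structure within \code{energyWindow} of the minimum is enumerated
#' by a bound-pruned recursion over the dynamic-programming table.
#' With \code{engine = "vienna"} the RNAfold/RNAsubopt command-line
#' tools are used instead. Structures are returned in deterministic
#' (energy, then lexicographic dot-bracket) order and always include
#' the MFE structure.
#'
#' @param sequence Nucleotide sequence (ACGT/U; length >= 5; no Ns).
#' @param engine \code{"toy"} (default) or \code{"vienna"}.
#' @param energyWindow Energy window above the MFE in kcal/mol
#'   (default 5).
#' @return A \linkS4class{StructureEnsemble}.
#' @examples
#' fold("GGGAAACCC")  # MFE structure (((...))), toy energy -3
#' @export
fold <- function(sequence, engine = c("toy", "vienna"), energyWindow = 5) {
  engine <- match.arg(engine)
  s <- .normalizeSeq(sequence, "sequence")
  if (grepl("N", s, fixed = TRUE)) stop("sequence contains N: cannot fold")
  if (nchar(s) < 5L) stop("sequence shorter than 5 nt")
  if (engine == "toy") {
    ch <- .seqChars(s)
    E <- .toyEnergyTable(ch)
    mfe <- E[1L, length(ch)]
    structs <- .enumerateInterval(ch, E, 1L, length(ch), mfe + energyWindow)
    db <- vapply(structs, .pairsToDotBracket, character(1), n = length(ch))
    en <- vapply(structs, function(p) -as.numeric(nrow(p)), numeric(1))
    ord <- order(en, db)
    db <- db[ord]; en <- en[ord]
    new("StructureEnsemble", sequence = s, mfeStructure = db[1L],
        mfe = mfe, structures = db, energies = en,
        energyWindow = energyWindow, engine = "toy")
  } else {
    if (!nzchar(Sys.which("RNAsubopt")) || !nzchar(Sys.which("RNAfold")))
      stop("RNAsubopt/RNAfold not found on PATH")
    rna <- chartr("T", "U", s)
    sub <- system2("RNAsubopt", args = c("-e", format(energyWindow)),
                   input = rna, stdout = TRUE, stderr = FALSE)
    sub <- sub[grepl("^[().]+\\s", sub)]
    parts <- strsplit(trimws(sub), "\\s+")
    db <- vapply(parts, `[`, character(1), 1L)
    en <- as.numeric(vapply(parts, `[`, character(1), 2L))
    ord <- order(en, db)
    db <- db[ord]; en <- en[ord]
    new("StructureEnsemble", sequence = s, mfeStructure = db[1L],
        mfe = en[1L], structures = db, energies = en,
        energyWindow = energyWindow, engine = "vienna")
  }
}

## dot-bracket -> 2-column pair matrix; errors on unbalanced input
.dotBracketPairs <- function(db) {
  ch <- .seqChars(db)
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    } else if (ch[i] != ".") stop("invalid character in dot-bracket string")
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

#' Abstract shape of a secondary structure
#'
#' A coarse, level-5-style abstraction: unpaired positions are
#' dropped, each maximal helix becomes one bracket pair, and helices
#' separated only by unpaired bases (bulges and internal loops) are
#' merged, so the shape records only the branching pattern. An open
#' chain maps to \code{"_"}.
#'
#' @param dotBracket Balanced dot-bracket string.
#' @return Shape string over \code{"["}, \code{"]"} and \code{"_"}.
#' @examples
#' abstractShape("((...))")             # "[]"
#' abstractShape("..((..))..((...))..") # "[][]"
#' abstractShape(".....")               # "_"
#' @export
abstractShape <- function(dotBracket) {
  pairs <- .dotBracketPairs(dotBracket)
  if (!nrow(pairs)) return("_")
  partner <- integer(nchar(dotBracket))
  partner[pairs[, 1L]] <- pairs[, 2L]
  partner[pairs[, 2L]] <- pairs[, 1L]
  topLevel <- function(from, to) {
    kids <- list()
    i <- from
    while (i <= to) {
      if (partner[i] > i) { kids[[length(kids) + 1L]] <- c(i, partner[i]); i <- partner[i] + 1L }
      else i <- i + 1L
    }
    kids
  }
  shapeOf <- function(open, close) {
    kids <- topLevel(open + 1L, close - 1L)
    if (length(kids) == 0L) return("[]")
    if (length(kids) == 1L) return(shapeOf(kids[[1L]][1L], kids[[1L]][2L]))
    paste0("[", paste(vapply(kids, function(k) shapeOf(k[1L], k[2L]),
                             character(1)), collapse = ""), "]")
  }
  ext <- topLevel(1L, nchar(dotBracket))
  paste(vapply(ext, function(k) shapeOf(k[1L], k[2L]), character(1)),
        collapse = "")
}

#' Census of abstract shapes over a structure ensemble
#'
#' @param ensemble A \linkS4class{StructureEnsemble}.
#' @return A list with \code{shapes} (data.frame \code{shape},
#'   \code{count}, counts summing to the ensemble size) and
#'   \code{n_shapes}.
#' @export
shapeCensus <- function(ensemble) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  if (!length(ensemble@structures)) stop("empty structure ensemble")
  sh <- vapply(ensemble@structures, abstractShape, character(1),
               USE.NAMES = FALSE)
  tab <- table(sh)
  list(shapes = data.frame(shape = names(tab),
                           count = as.integer(tab),
                           stringsAsFactors = FALSE),
       n_shapes = length(tab))
}

## maximal helices (runs of directly stacked pairs) of a structure
.helices <- function(dotBracket) {
  pairs <- .dotBracketPairs(dotBracket)
  if (!nrow(pairs)) return(list())
  key <- paste(pairs[, 1L], pairs[, 2L])
  helices <- list()
  used <- rep(FALSE, nrow(pairs))
  lookup <- setNames(seq_len(nrow(pairs)), key)
  for (r in seq_len(nrow(pairs))) {
    if (used[r]) next
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    ## only start a helix at its outermost pair
    if (!is.na(lookup[paste(i - 1L, j + 1L)])) next
    h <- matrix(integer(0), 0, 2)
    repeat {
      idx <- lookup[paste(i, j)]
      if (is.na(idx)) break
      used[idx] <- TRUE
      h <- rbind(h, c(i, j))
      i <- i + 1L; j <- j - 1L
    }
    helices[[length(helices) + 1L]] <- h
  }
  helices
}

#' Helices conserved across the suboptimal ensemble
#'
#' Maximal helices of the MFE structure whose complete base-pair set is
#' present in at least \code{fraction} of the ensemble's structures
#' (the MFE structure included), mirroring the idea of structural
#' elements shared by most low-energy folds.
#'
#' @param ensemble A \linkS4class{StructureEnsemble}.
#' @param fraction Required fraction of structures, in (0, 1]
#'   (default 0.6).
#' @return A list of conserved helices, each a 2-column matrix of base
#'   pairs with a \code{"support"} attribute (fraction of structures
#'   containing it).
#' @export
conservedElements <- function(ensemble, fraction = 0.6) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  helices <- .helices(ensemble@mfeStructure)
  if (!length(helices)) return(list())
  pairSets <- lapply(ensemble@structures, function(db) {
    p <- .dotBracketPairs(db)
    paste(p[, 1L], p[, 2L])
  })
  keep <- list()
  for (h in helices) {
    hk <- paste(h[, 1L], h[, 2L])
    support <- mean(vapply(pairSets, function(ps) all(hk %in% ps), logical(1)))
    if (support >= fraction) {
      attr(h, "support") <- support
      keep[[length(keep) + 1L]] <- h
    }
  }
  keep
}
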