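#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show slot
#' @importFrom stats cor.test lm predict pbinom runif setNames
#' @importFrom utils write.table read.delim head packageVersion
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

## normalise a nucleotide string: uppercase, U -> T; validate against ACGTN
.normalizeSeq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string")
  s <- chartr("u", "U", toupper(x))
  s <- chartr("U", "T", s)
  bad <- gregexpr("[^ACGTN]", s)[[1L]]
  if (bad[1L] != -1L)
    stop("non-IUPAC characters in ", what, " at position(s) ",
         paste(bad, collapse = ", "))
  if (nchar(s) == 0L) stop(what, " is empty")
  s
}

.seqChars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.revcomp <- function(s) {
  paste(rev(.seqChars(chartr("ACGT", "TGCA", s))), collapse = "")
}

## run code under a fixed RNG state, restoring the caller's stream afterwards
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## derive a per-unit substream seed from a global seed; kept below 2^31 - 1
.deriveSeed <- function(seed, index) {
  x <- ((as.double(seed) %% 2147483647) * 2654435 +
          as.double(index) * 97 + 1) %% 2147483647
  as.integer(x)
}

## all start positions of fixed-width motif hits (overlapping), 1-based
.motifHits <- function(seq, motif) {
  if (nchar(seq) < nchar(motif)) return(integer(0))
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}
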