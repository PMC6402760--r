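#' UtrCatalog: a keyed catalog of UTR/CDS variant sequences
#'
#' Container for a set of sequence records keyed by
#' (gene, variant, species, region). Sequences are stored as a
#' \linkS4class{DNAStringSet} whose \code{mcols} carry the key columns;
#' the region is one of \code{"five_prime"}, \code{"three_prime"} or
#' \code{"cds"}. An optional background set (e.g. a random UTR sample
#' standing in for a general UTR database) can be attached for
#' composition comparisons.
#'
#' @slot sequences A \code{DNAStringSet} with mcols columns
#'   \code{gene}, \code{variant}, \code{species}, \code{region}.
#' @slot background A \code{DNAStringSet} (possibly empty).
#'
#' @importClassesFrom Biostrings DNAStringSet
#' @exportClass UtrCatalog
setClass("UtrCatalog",
  representation(sequences = "DNAStringSet", background = "DNAStringSet"))

setValidity("UtrCatalog", function(object) {
  md <- S4Vectors::mcols(object@sequences)
  need <- c("gene", "variant", "species", "region")
  if (is.null(md) || !all(need %in% colnames(md)))
    return("mcols(sequences) must contain gene, variant, species, region")
  if (length(object@sequences)) {
    if (!all(md$region %in% c("five_prime", "three_prime", "cds")))
      return("region must be five_prime, three_prime or cds")
    key <- paste(md$gene, md$variant, md$species, md$region, sep = "\r")
    if (anyDuplicated(key))
      return("duplicate (gene, variant, species, region) keys")
    if (any(Biostrings::width(object@sequences) < 1L))
      return("zero-length sequence in catalog")
  }
  TRUE
})

#' Construct a UtrCatalog
#'
#' @param sequences Character vector or \code{DNAStringSet} of sequences
#'   (U is mapped to T).
#' @param gene,variant,species Character vectors recycled to the number
#'   of sequences.
#' @param region Region label for all records, or a vector.
#' @param background Optional character vector / \code{DNAStringSet} of
#'   background sequences.
#' @return A \linkS4class{UtrCatalog}.
#' @examples
#' UtrCatalog("ACGTACGT", gene = "APOD", variant = "b",
#'            species = "Hsap", region = "five_prime")
#' @export
UtrCatalog <- function(sequences, gene, variant, species, region,
                       background = NULL) {
  if (is(sequences, "DNAStringSet")) {
    seqs <- sequences
  } else {
    seqs <- Biostrings::DNAStringSet(
      vapply(as.character(sequences), .normalizeSeq, character(1)))
  }
  n <- length(seqs)
  md <- S4Vectors::DataFrame(
    gene = rep_len(as.character(gene), n),
    variant = rep_len(as.character(variant), n),
    species = rep_len(as.character(species), n),
    region = rep_len(as.character(region), n))
  names(seqs) <- paste(md$gene, md$variant, md$species, sep = "|")
  S4Vectors::mcols(seqs) <- md
  bg <- if (is.null(background)) Biostrings::DNAStringSet() else
    if (is(background, "DNAStringSet")) background else
      Biostrings::DNAStringSet(
        vapply(as.character(background), .normalizeSeq, character(1)))
  new("UtrCatalog", sequences = seqs, background = bg)
}

#' @describeIn UtrCatalog Number of records.
#' @param x A \code{UtrCatalog}.
#' @export
setMethod("length", "UtrCatalog", function(x) length(x@sequences))

#' Catalog accessors
#'
#' \code{catalogSequences} returns the underlying \code{DNAStringSet};
#' \code{catalogMeta} the key metadata as a \code{DataFrame};
#' \code{catalogBackground} the attached background set.
#'
#' @param x A \linkS4class{UtrCatalog}.
#' @return See description.
#' @export
catalogSequences <- function(x) {
  stopifnot(is(x, "UtrCatalog"))
  x@sequences
}

#' @rdname catalogSequences
#' @export
catalogMeta <- function(x) {
  stopifnot(is(x, "UtrCatalog"))
  S4Vectors::mcols(x@sequences)
}

#' @rdname catalogSequences
#' @export
catalogBackground <- function(x) {
  stopifnot(is(x, "UtrCatalog"))
  x@background
}

#' Look up one record by key
#'
#' @param x A \linkS4class{UtrCatalog}.
#' @param gene,variant,species,region Key components; \code{NULL}
#'   components are not filtered on.
#' @return A \code{UtrCatalog} with the matching records (at most one
#'   when all four components are given).
#' @export
catalogLookup <- function(x, gene = NULL, variant = NULL, species = NULL,
                          region = NULL) {
  md <- catalogMeta(x)
  keep <- rep(TRUE, length(x))
  if (!is.null(gene)) keep <- keep & md$gene %in% gene
  if (!is.null(variant)) keep <- keep & md$variant %in% variant
  if (!is.null(species)) keep <- keep & md$species %in% species
  if (!is.null(region)) keep <- keep & md$region %in% region
  new("UtrCatalog", sequences = x@sequences[keep], background = x@background)
}

setMethod("show", "UtrCatalog", function(object) {
  md <- catalogMeta(object)
  cat("UtrCatalog with", length(object), "record(s)")
  if (length(object))
    cat(" (", paste(unique(md$region), collapse = ", "), ")", sep = "")
  cat("\n")
  if (length(object)) {
    n <- min(length(object), 5L)
    for (i in seq_len(n))
      cat(sprintf("  %s|%s|%s [%s] %d nt\n", md$gene[i], md$variant[i],
                  md$species[i], md$region[i],
                  Biostrings::width(object@sequences)[i]))
    if (length(object) > n) cat("  ...\n")
  }
  if (length(object@background))
    cat("  background:", length(object@background), "sequence(s)\n")
})

#' IdentityMatrix: pairwise percent identity over labeled sequences
#'
#' Symmetric matrix of percent identities with a 100 diagonal, plus the
#' method used to obtain it (\code{pairwise_global} alignments or
#' \code{msa_columns} over a pre-built alignment).
#'
#' @slot values Numeric matrix, symmetric, diagonal 100.
#' @slot method Character scalar.
#' @exportClass IdentityMatrix
setClass("IdentityMatrix",
  representation(values = "matrix", method = "character"))

setValidity("IdentityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8))) return("matrix must be symmetric")
  if (nrow(v) && !isTRUE(all.equal(unname(diag(v)), rep(100, nrow(v)))))
    return("diagonal must be 100")
  if (any(v < -1e-8 | v > 100 + 1e-8)) return("identities must lie in [0, 100]")
  if (!object@method %in% c("pairwise_global", "msa_columns"))
    return("method must be pairwise_global or msa_columns")
  TRUE
})

#' @rdname IdentityMatrix-class
#' @param x An \code{IdentityMatrix}.
#' @export
identityValues <- function(x) {
  stopifnot(is(x, "IdentityMatrix"))
  x@values
}

#' @rdname IdentityMatrix-class
#' @export
identityMethod <- function(x) {
  stopifnot(is(x, "IdentityMatrix"))
  x@method
}

setMethod("show", "IdentityMatrix", function(object) {
  cat("IdentityMatrix (", object@method, ") over ", nrow(object@values),
      " sequences\n", sep = "")
  print(round(object@values, 1))
})

#' GcCorrelation: UTR vs CDS G+C correlation summary
#'
#' Pearson correlation with two-sided p-value and ordinary
#' least-squares regression line, plus a pointwise 95 percent
#' confidence band evaluated at the observed x values.
#'
#' @slot r Pearson correlation coefficient.
#' @slot pValue Two-sided p-value.
#' @slot slope,intercept OLS regression line.
#' @slot n Number of pairs.
#' @slot band data.frame with columns x, fit, lwr, upr.
#' @exportClass GcCorrelation
setClass("GcCorrelation",
  representation(r = "numeric", pValue = "numeric", slope = "numeric",
                 intercept = "numeric", n = "integer", band = "data.frame"))

setMethod("show", "GcCorrelation", function(object) {
  cat(sprintf("GcCorrelation: r = %.4f, p = %.3g, n = %d\n",
              object@r, object@pValue, object@n))
  cat(sprintf("  fit: y = %.4f x + %.4f\n", object@slope, object@intercept))
})

#' StructureEnsemble: MFE and suboptimal secondary structures
#'
#' The minimum-free-energy structure of a sequence together with all
#' suboptimal structures within an energy window, in deterministic
#' (energy, then lexicographic dot-bracket) order.
#'
#' @slot sequence The folded sequence (DNA alphabet, read as RNA).
#' @slot mfeStructure Dot-bracket string of the MFE structure.
#' @slot mfe MFE in kcal/mol (toy engine: -1 per base pair).
#' @slot structures Character vector of dot-bracket strings.
#' @slot energies Numeric vector parallel to \code{structures}.
#' @slot energyWindow Energy window above the MFE, kcal/mol.
#' @slot engine Engine label ("toy" or "vienna").
#' @exportClass StructureEnsemble
setClass("StructureEnsemble",
  representation(sequence = "character", mfeStructure = "character",
                 mfe = "numeric", structures = "character",
                 energies = "numeric", energyWindow = "numeric",
                 engine = "character"))

setValidity("StructureEnsemble", function(object) {
  n <- nchar(object@sequence)
  if (length(object@structures) != length(object@energies))
    return("structures and energies must be parallel")
  if (any(nchar(object@structures) != n))
    return("every structure must have the sequence's length")
  if (length(object@energies)) {
    if (any(object@energies < object@mfe - 1e-6))
      return("no suboptimal energy may undercut the MFE")
    if (any(object@energies > object@mfe + object@energyWindow + 1e-6))
      return("suboptimal energies must lie within the energy window")
  }
  TRUE
})

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble (%s engine): %d nt, MFE %.2f kcal/mol, %d structure(s) within +%.1f\n",
              object@engine, nchar(object@sequence), object@mfe,
              length(object@structures), object@energyWindow))
  cat(" ", object@sequence, "\n ", object@mfeStructure, "\n")
})

#' @rdname StructureEnsemble-class
#' @param x A \code{StructureEnsemble}.
#' @export
ensembleStructures <- function(x) {
  stopifnot(is(x, "StructureEnsemble"))
  x@structures
}

#' @rdname StructureEnsemble-class
#' @export
ensembleEnergies <- function(x) {
  stopifnot(is(x, "StructureEnsemble"))
  x@energies
}

#' @rdname StructureEnsemble-class
#' @export
mfeStructure <- function(x) {
  stopifnot(is(x, "StructureEnsemble"))
  x@mfeStructure
}

#' @rdname StructureEnsemble-class
#' @export
mfeEnergy <- function(x) {
  stopifnot(is(x, "StructureEnsemble"))
  x@mfe
}
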