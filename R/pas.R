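#' Default set of rare polyadenylation-signal hexamer variants
#'
#' The single-base variants of AAUAAA (DNA alphabet) reported as
#' functional low-frequency signals in genome-wide polyadenylation
#' surveys. The canonical AATAAA and the main non-canonical ATTAAA are
#' typed separately (C and NC); everything in this set is typed NC*.
#'
#' @return Character vector of hexamers.
#' @export
pasVariantHexamers <- function() {
  c("TATAAA", "AGTAAA", "AAGAAA", "AATATA", "AATACA", "CATAAA",
    "GATAAA", "AATGAA", "TTTAAA", "ACTAAA", "AATAGA")
}

#' Scan a 3' UTR for polyadenylation signals
#'
#' All sense-strand occurrences of the canonical hexamer AATAAA (type
#' C), the non-canonical ATTAAA (type NC), and each configured variant
#' (type NC*), in ascending position; overlapping hits are allowed.
#'
#' @param utr3 3' UTR sequence (length >= 6).
#' @param variantSet NC* hexamers (default
#'   \code{\link{pasVariantHexamers}}).
#' @param classify Also fill in \code{distance_to_end} and
#'   \code{efficiency} using \code{\link{classifyPasEfficiency}}
#'   (default TRUE).
#' @param window Efficiency window passed on when \code{classify}.
#' @return A \code{DataFrame} with columns \code{position} (1-based
#'   start of the hexamer), \code{hexamer}, \code{pas_type}, and when
#'   classified \code{distance_to_end} and \code{efficiency}.
#' @examples
#' scanPas("CCAATAAACCCC")
#' @export
scanPas <- function(utr3, variantSet = pasVariantHexamers(),
                    classify = TRUE, window = c(10, 45)) {
  s <- .normalizeSeq(utr3, "utr3")
  if (nchar(s) < 6L) stop("utr3 shorter than a hexamer")
  hexes <- c(AATAAA = "C", ATTAAA = "NC",
             setNames(rep("NC_star", length(variantSet)), variantSet))
  hits <- do.call(rbind, lapply(names(hexes), function(h) {
    p <- .motifHits(s, h)
    if (!length(p)) return(NULL)
    data.frame(position = p, hexamer = h, pas_type = unname(hexes[[h]]))
  }))
  if (is.null(hits))
    hits <- data.frame(position = integer(0), hexamer = character(0),
                       pas_type = character(0))
  hits <- hits[order(hits$position, hits$hexamer), , drop = FALSE]
  rownames(hits) <- NULL
  out <- S4Vectors::DataFrame(hits)
  if (classify) {
    out$distance_to_end <- nchar(s) - out$position
    out$efficiency <- classifyPasEfficiency(out$position, out$pas_type,
                                            nchar(s), window = window)
  }
  out
}

#' Classify polyadenylation efficiency from position and type
#'
#' A signal whose distance to the 3' end (UTR length minus hexamer
#' start) falls inside the window is called very efficient (VE) when
#' canonical and efficient (E) when non-canonical (NC or NC*); signals
#' outside the window are low efficiency (LE). The default window of
#' 10-45 nt covers the distances at which canonical signals are
#' reported as very efficient in the reference annotations bundled
#' with this package.
#'
#' @param position 1-based hexamer start position(s).
#' @param pasType \code{"C"}, \code{"NC"} or \code{"NC_star"}
#'   (recycled).
#' @param utrLength UTR length in nt.
#' @param window Numeric \code{c(min, max)} distance window, min < max.
#' @return Character vector of \code{"VE"}, \code{"E"}, \code{"LE"}.
#' @examples
#' classifyPasEfficiency(191, "C", 214)   # "VE"
#' classifyPasEfficiency(142, "C", 639)   # "LE"
#' @export
classifyPasEfficiency <- function(position, pasType, utrLength,
                                  window = c(10, 45)) {
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("window must be c(min, max) with min < max")
  d <- utrLength - position
  inside <- d >= window[1L] & d <= window[2L]
  ifelse(!inside, "LE", ifelse(rep_len(pasType, length(d)) == "C", "VE", "E"))
}

#' Infer candidate alternative 3' ends from polyadenylation signals
#'
#' Cleavage is expected a short distance downstream of a functional
#' signal: each non-LE site proposes a 3' end at hexamer end + offset,
#' capped at the UTR length. Candidates are deduplicated and returned
#' ascending.
#'
#' @param sites A \code{DataFrame}/data.frame from \code{\link{scanPas}}
#'   with \code{position} and \code{efficiency} columns.
#' @param utrLength UTR length in nt.
#' @param offset Downstream cleavage offset in nt (default 20).
#' @return Integer vector of candidate 3'-end coordinates (possibly
#'   empty).
#' @export
inferAlternativeEnds <- function(sites, utrLength, offset = 20L) {
  sites <- as.data.frame(sites)
  if (!nrow(sites)) return(integer(0))
  keep <- sites$efficiency != "LE"
  if (!any(keep)) return(integer(0))
  ends <- pmin(sites$position[keep] + 5L + as.integer(offset),
               as.integer(utrLength))
  sort(unique(as.integer(ends)))
}
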