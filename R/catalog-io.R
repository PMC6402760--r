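#' Read a UTR/CDS catalog from FASTA
#'
#' Headers must follow the \code{gene|variant|species} convention
#' (delimiter configurable). Sequences are uppercased and U is mapped
#' to T so RNA input is accepted; the resulting records all carry the
#' given region label. Duplicate keys, malformed headers, empty files
#' and non-IUPAC characters are errors.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param region One of \code{"five_prime"}, \code{"three_prime"},
#'   \code{"cds"}.
#' @param delim Header field delimiter (default \code{"|"}).
#' @param background Optional FASTA path for a background sequence set.
#' @return A \linkS4class{UtrCatalog}.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">APOD|b|Hsap", "ACGUACGU"), f)
#' readUtrCatalog(f, region = "five_prime")
#' @export
readUtrCatalog <- function(path, region = c("five_prime", "three_prime", "cds"),
                           delim = "|", background = NULL) {
  region <- match.arg(region)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- sub("\\s.*$", "", names(raw))
  fields <- strsplit(headers, delim, fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed header (expected gene", delim, "variant", delim,
         "species): '", headers[which(bad)[1L]], "'")
  gene <- vapply(fields, `[`, character(1), 1L)
  variant <- vapply(fields, `[`, character(1), 2L)
  species <- vapply(fields, `[`, character(1), 3L)
  key <- paste(gene, variant, species, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate record key in ", path, ": '",
         headers[which(duplicated(key))[1L]], "'")
  seqs <- vapply(seq_along(raw), function(i) {
    tryCatch(.normalizeSeq(as.character(raw[[i]])),
             error = function(e) stop("record '", headers[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, character(1))
  bg <- NULL
  if (!is.null(background)) {
    braw <- Biostrings::readBStringSet(background)
    bg <- vapply(seq_along(braw), function(i)
      .normalizeSeq(as.character(braw[[i]])), character(1))
  }
  UtrCatalog(seqs, gene = gene, variant = variant, species = species,
             region = region, background = bg)
}

#' Write a catalog back to FASTA
#'
#' Inverse of \code{\link{readUtrCatalog}} up to line wrapping; headers
#' are rebuilt as \code{gene|variant|species}.
#'
#' @param x A \linkS4class{UtrCatalog}.
#' @param path Output path.
#' @param delim Header delimiter.
#' @return Invisibly, \code{path}.
#' @export
writeUtrCatalog <- function(x, path, delim = "|") {
  md <- catalogMeta(x)
  seqs <- catalogSequences(x)
  lines <- character(0)
  for (i in seq_len(length(x)))
    lines <- c(lines,
               paste0(">", paste(md$gene[i], md$variant[i], md$species[i],
                                 sep = delim)),
               as.character(seqs[[i]]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a feature table as TSV
#'
#' Rows must share one column schema. Output is tab-separated with a
#' header line, floats printed with 2 decimals, and deterministic row
#' order (gene, variant, species when those columns are present), so
#' that identical row sets produce identical bytes regardless of input
#' order.
#'
#' @param rows A data.frame or \code{DataFrame} (or list of rows
#'   sharing the same names).
#' @param path Output path.
#' @param comment Optional character vector of comment lines written
#'   before the header, each prefixed with \code{"# "}.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureTable <- function(rows, path, comment = NULL) {
  if (is(rows, "DataFrame")) rows <- as.data.frame(rows)
  if (is.list(rows) && !is.data.frame(rows)) {
    if (length(rows)) {
      schema <- names(rows[[1L]])
      ok <- vapply(rows, function(r) identical(names(r), schema), logical(1))
      if (!all(ok)) stop("inconsistent row schemas")
      rows <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      rows <- data.frame()
    }
  }
  if (nrow(rows)) {
    ord <- intersect(c("gene", "variant", "species"), colnames(rows))
    if (length(ord))
      rows <- rows[do.call(order, rows[ord]), , drop = FALSE]
    for (j in seq_along(rows))
      if (is.double(rows[[j]])) rows[[j]] <- sprintf("%.2f", rows[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
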