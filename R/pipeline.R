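#' Build a run configuration for the characterization pipeline
#'
#' Every threshold defaults to the corresponding module default, so an
#' empty configuration reproduces the documented behaviour of each
#' stage.
#'
#' @param utr5,utr3,cds,mirnas Input FASTA paths (any may be NULL;
#'   stages without input are disabled).
#' @param orthologDir Optional directory of per-gene ortholog FASTAs
#'   for the conservation report.
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed recorded in the log and used by any
#'   randomized stage.
#' @param minCodons,requireStopInUtr uORF stage settings.
#' @param pasWindow,pasVariants PAS stage settings.
#' @param kmerK,kmerOrder k-mer stage settings.
#' @param mirnaSeed,mirnaGU,mirnaMismatch,mirnaFlank miRNA stage
#'   settings.
#' @param energyEngine \code{"stub"} is not meaningful here, so one of
#'   \code{"none"}, \code{"toy"}, \code{"vienna"}: engine used for MFE
#'   and miRNA accessibility (default \code{"toy"} when miRNAs are
#'   supplied, else \code{"none"}).
#' @param cart Thresholds from \code{\link{cartThresholds}}.
#' @return A list with class \code{"RunConfig"}.
#' @export
runConfig <- function(utr5 = NULL, utr3 = NULL, cds = NULL, mirnas = NULL,
                      orthologDir = NULL, outDir = tempfile("utrlens_run_"),
                      seed = 1L, minCodons = 1L, requireStopInUtr = TRUE,
                      pasWindow = c(10, 45),
                      pasVariants = pasVariantHexamers(),
                      kmerK = 6L, kmerOrder = 2L,
                      mirnaSeed = 8L, mirnaGU = 1L, mirnaMismatch = 1L,
                      mirnaFlank = 70L,
                      energyEngine = if (is.null(mirnas)) "none" else "toy",
                      cart = cartThresholds()) {
  cfg <- list(utr5 = utr5, utr3 = utr3, cds = cds, mirnas = mirnas,
              orthologDir = orthologDir, outDir = outDir,
              seed = as.integer(seed), minCodons = minCodons,
              requireStopInUtr = requireStopInUtr, pasWindow = pasWindow,
              pasVariants = pasVariants, kmerK = kmerK,
              kmerOrder = kmerOrder, mirnaSeed = mirnaSeed,
              mirnaGU = mirnaGU, mirnaMismatch = mirnaMismatch,
              mirnaFlank = mirnaFlank, energyEngine = energyEngine,
              cart = cart)
  class(cfg) <- "RunConfig"
  cfg
}

.cfgEngine <- function(cfg) {
  switch(cfg$energyEngine,
         none = NULL, toy = toyEnergyEngine(), vienna = viennaEnergyEngine(),
         stop("unknown energy engine: ", cfg$energyEngine))
}

#' Run the full UTR characterization pipeline
#'
#' Reads the configured catalogs, runs every enabled stage and writes
#' per-gene report tables to the output directory:
#' \code{table1_like.tsv} (5' UTR features: length, \%G+C, uAUG/uORF
#' counts, O/W efficiency and context strings, translation class),
#' \code{table4_like.tsv} (3' UTR features: polyadenylation sites with
#' type and efficiency, plus accessible / very accessible miRNA target
#' counts when miRNAs are supplied), \code{enrichment.tsv}
#' (over-represented k-mers of the 5' UTR set), \code{conservation.tsv}
#' (pairwise identities per ortholog FASTA, when provided) and
#' \code{run_log.txt}. Missing inputs for an enabled stage raise an
#' error before any computation; identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config A \code{\link{runConfig}}.
#' @return Invisibly, a named list of the tables written (as
#'   data.frames) plus the output paths.
#' @export
runCharacterization <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  for (p in c(config$utr5, config$utr3, config$cds, config$mirnas))
    if (!file.exists(p)) stop("input not found: ", p)
  if (!is.null(config$orthologDir) && !dir.exists(config$orthologDir))
    stop("input not found: ", config$orthologDir)
  if (is.null(config$utr5) && is.null(config$utr3))
    stop("at least one UTR input is required")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  engine <- .cfgEngine(config)
  out <- list(outDir = config$outDir)

  if (!is.null(config$utr5)) {
    cat5 <- readUtrCatalog(config$utr5, region = "five_prime")
    md <- catalogMeta(cat5)
    seqs <- as.character(catalogSequences(cat5))
    rows <- lapply(seq_len(length(cat5)), function(i) {
      prof <- translationProfile(seqs[i], minCodons = config$minCodons,
                                 requireStopInUtr = config$requireStopInUtr,
                                 thresholds = config$cart)
      mfe <- NA_real_
      if (!is.null(engine) && config$energyEngine == "toy")
        mfe <- .nussinovMinEnergy(seqs[i])
      if (config$energyEngine == "vienna")
        mfe <- mfeEnergy(fold(seqs[i], engine = "vienna"))
      cls <- assignTranslationClass(prof$n_uorf, prof$length,
                                    mfePerNt = if (is.na(mfe)) NA_real_
                                               else mfe / prof$length,
                                    thresholds = config$cart)
      data.frame(gene = md$gene[i], variant = md$variant[i],
                 species = md$species[i], length = prof$length,
                 gc_percent = prof$gc_percent, mfe = mfe,
                 n_uaug = prof$n_uaug, n_uorf = prof$n_uorf,
                 efficiency = prof$efficiency_string,
                 context = prof$context_string, cart_class = cls)
    })
    t1 <- do.call(rbind, rows)
    writeFeatureTable(t1, file.path(config$outDir, "table1_like.tsv"),
                      comment = paste("engine:", config$energyEngine))
    out$table1 <- t1

    enr <- kmerEnrichment(seqs, k = config$kmerK, order = config$kmerOrder)
    writeFeatureTable(as.data.frame(enr),
                      file.path(config$outDir, "enrichment.tsv"))
    out$enrichment <- as.data.frame(enr)
  }

  if (!is.null(config$utr3)) {
    cat3 <- readUtrCatalog(config$utr3, region = "three_prime")
    md <- catalogMeta(cat3)
    seqs <- as.character(catalogSequences(cat3))
    mirnas <- NULL
    if (!is.null(config$mirnas)) {
      mset <- Biostrings::readBStringSet(config$mirnas)
      mirnas <- setNames(vapply(seq_along(mset), function(i)
        .normalizeSeq(as.character(mset[[i]])), character(1)),
        sub("\\s.*$", "", names(mset)))
    }
    rows <- lapply(seq_len(length(cat3)), function(i) {
      sites <- scanPas(seqs[i], variantSet = config$pasVariants,
                       window = config$pasWindow)
      base <- data.frame(gene = md$gene[i], variant = md$variant[i],
                         species = md$species[i], length = nchar(seqs[i]))
      pas <- if (nrow(sites)) data.frame(
        pas_position = sites$position, pas_type = sites$pas_type,
        pas_efficiency = sites$efficiency)
      else data.frame(pas_position = NA_integer_, pas_type = NA_character_,
                      pas_efficiency = NA_character_)
      tab <- cbind(base[rep(1L, nrow(pas)), , drop = FALSE], pas)
      if (!is.null(mirnas) && !is.null(engine)) {
        nacc <- 0L; nvery <- 0L
        for (mi in seq_along(mirnas)) {
          cand <- findSeedMatches(mirnas[[mi]], seqs[i],
                                  minSeed = config$mirnaSeed,
                                  maxGU = config$mirnaGU,
                                  maxMismatch = config$mirnaMismatch)
          if (nrow(cand)) {
            scored <- scoreSites(cand, seqs[i], mirnas[[mi]], engine,
                                 flank = config$mirnaFlank)
            cls <- classifyTargets(scored)
            nacc <- nacc + cls[["n_accessible"]]
            nvery <- nvery + cls[["n_very_accessible"]]
          }
        }
        tab$n_accessible <- nacc
        tab$n_very_accessible <- nvery
      }
      tab
    })
    t4 <- do.call(rbind, rows)
    rownames(t4) <- NULL
    writeFeatureTable(t4, file.path(config$outDir, "table4_like.tsv"),
                      comment = paste("engine:", config$energyEngine))
    out$table4 <- t4
  }

  if (!is.null(config$orthologDir)) {
    files <- sort(list.files(config$orthologDir,
                             pattern = "\\.(fa|fasta)$", full.names = TRUE))
    crows <- list()
    for (f in files) {
      fam <- Biostrings::readBStringSet(f)
      seqsf <- setNames(vapply(seq_along(fam), function(i)
        .normalizeSeq(as.character(fam[[i]])), character(1)),
        sub("\\s.*$", "", names(fam)))
      im <- distanceMatrix(seqsf, mode = "pairwise_global")
      v <- identityValues(im)
      for (i in seq_len(nrow(v) - 1L))
        for (j in seq.int(i + 1L, ncol(v)))
          crows[[length(crows) + 1L]] <- data.frame(
            family = sub("\\.(fa|fasta)$", "", basename(f)),
            a = rownames(v)[i], b = colnames(v)[j],
            identity = v[i, j],
            homolog = homologyCall(v[i, j]))
    }
    cons <- if (length(crows)) do.call(rbind, crows) else
      data.frame(family = character(0), a = character(0), b = character(0),
                 identity = numeric(0), homolog = logical(0))
    writeFeatureTable(cons, file.path(config$outDir, "conservation.tsv"))
    out$conservation <- cons
  }

  log <- c(paste("utrlens version:", as.character(packageVersion("utrlens"))),
           paste("seed:", config$seed),
           paste("energy engine:", config$energyEngine),
           paste("pas window:", paste(config$pasWindow, collapse = "-")),
           paste("kmer k:", config$kmerK, "order:", config$kmerOrder),
           paste("inputs:",
                 paste(c(config$utr5, config$utr3, config$cds,
                         config$mirnas), collapse = " ")))
  writeLines(log, file.path(config$outDir, "run_log.txt"))
  invisible(out)
}
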