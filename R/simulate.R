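#' Build and validate a simulation plan
#'
#' A plan fixes everything the generator does: sizes, base
#' composition, the features planted into each simulated gene, and the
#' divergence model for ortholog families. The same plan and seed
#' always produce byte-identical output. Planted features may not
#' overlap (a minimum 5 nt gap is enforced) and infeasible plans are
#' rejected up front.
#'
#' @param seed Integer master seed; per-gene substreams are derived
#'   from it.
#' @param nGenes Number of genes.
#' @param variantsPerGene Alternative UTR variants per gene (variant
#'   suffixes "a", "b", ...).
#' @param utr5Length,utr3Length Lengths in nt.
#' @param cdsCodons CDS length in codons (start and stop included).
#' @param gcTarget Background G+C fraction.
#' @param plantedUorfs data.frame with \code{cap_distance},
#'   \code{context_class} ("optimal", "adequate", "weak") and
#'   \code{peptide_length} (codons incl. start; >= 2 for optimal
#'   context, whose +4 base must be G).
#' @param plantedPas data.frame with \code{hexamer} and
#'   \code{distance_to_end}.
#' @param plantedKmers data.frame with \code{kmer} (no ATG inside) and
#'   \code{copies}; copies are planted into the 5' UTR downstream of
#'   any uORFs.
#' @param plantedMirnaSites data.frame with \code{mirna} (sequence,
#'   5'->3') and \code{site_start} (1-based 3' UTR position of the
#'   8-nt seed-paired region).
#' @param divergence Optional list \code{list(rates = c(pos1, pos2,
#'   pos3, utr), species = c(...))} used by
#'   \code{\link{divergeFamily}}.
#' @param species Species label for the root records.
#' @return A validated plan (list with class \code{"SimulationPlan"}).
#' @export
simulationPlan <- function(seed = 1L, nGenes = 5L, variantsPerGene = 1L,
                           utr5Length = 300L, utr3Length = 300L,
                           cdsCodons = 100L, gcTarget = 0.5,
                           plantedUorfs = NULL, plantedPas = NULL,
                           plantedKmers = NULL, plantedMirnaSites = NULL,
                           divergence = NULL, species = "SimSp") {
  plan <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
               variantsPerGene = as.integer(variantsPerGene),
               utr5Length = as.integer(utr5Length),
               utr3Length = as.integer(utr3Length),
               cdsCodons = as.integer(cdsCodons), gcTarget = gcTarget,
               plantedUorfs = plantedUorfs, plantedPas = plantedPas,
               plantedKmers = plantedKmers,
               plantedMirnaSites = plantedMirnaSites,
               divergence = divergence, species = species)
  class(plan) <- "SimulationPlan"
  .validatePlan(plan)
  plan
}

.featureGap <- 5L

.validatePlan <- function(plan) {
  stopifnot(plan$nGenes >= 1L, plan$variantsPerGene >= 1L,
            plan$gcTarget > 0, plan$gcTarget < 1,
            plan$utr5Length >= 10L, plan$utr3Length >= 10L,
            plan$cdsCodons >= 3L)
  spans5 <- NULL
  if (!is.null(plan$plantedUorfs)) {
    u <- plan$plantedUorfs
    stopifnot(all(c("cap_distance", "context_class", "peptide_length")
                  %in% names(u)))
    if (any(u$peptide_length < 1L)) stop("peptide_length must be >= 1")
    if (any(u$context_class == "optimal" & u$peptide_length < 2L))
      stop("optimal context needs peptide_length >= 2 (the +4 base must be G, but a stop codon starts with T)")
    if (any(u$context_class %in% c("optimal", "adequate") & u$cap_distance < 3L))
      stop("context classes requiring the -3 base need cap_distance >= 3")
    start <- u$cap_distance + 1L
    end <- u$cap_distance + 3L * (u$peptide_length + 1L)
    if (any(end > plan$utr5Length))
      stop("planted uORF exceeds the 5' UTR length")
    spans5 <- cbind(pmax(start - 3L, 1L), end)  # include the -3 context base
  }
  if (!is.null(plan$plantedKmers)) {
    k <- plan$plantedKmers
    stopifnot(all(c("kmer", "copies") %in% names(k)))
    if (any(grepl("ATG", k$kmer)))
      stop("planted k-mers must not contain ATG (would plant spurious uAUGs)")
    need <- sum((nchar(k$kmer) + .featureGap) * k$copies)
    free <- plan$utr5Length -
      (if (is.null(spans5)) 0L else max(spans5[, 2L])) - .featureGap
    if (need > free) stop("planted k-mer copies do not fit in the 5' UTR")
  }
  spans3 <- NULL
  if (!is.null(plan$plantedPas)) {
    p <- plan$plantedPas
    stopifnot(all(c("hexamer", "distance_to_end") %in% names(p)))
    if (any(nchar(p$hexamer) != 6L)) stop("PAS hexamers must be 6 nt")
    pos <- plan$utr3Length - p$distance_to_end
    if (any(pos < 1L | pos > plan$utr3Length - 5L))
      stop("planted PAS does not fit in the 3' UTR")
    spans3 <- cbind(pos, pos + 5L)
  }
  if (!is.null(plan$plantedMirnaSites)) {
    m <- plan$plantedMirnaSites
    stopifnot(all(c("mirna", "site_start") %in% names(m)))
    if (any(nchar(m$mirna) < 8L)) stop("miRNAs must be >= 8 nt")
    if (any(m$site_start < 1L | m$site_start + 7L > plan$utr3Length))
      stop("planted miRNA site does not fit in the 3' UTR")
    spans3 <- rbind(spans3, cbind(m$site_start, m$site_start + 7L))
  }
  .checkGaps(spans5, "5' UTR")
  .checkGaps(spans3, "3' UTR")
  if (!is.null(plan$divergence)) {
    stopifnot(all(c("rates", "species") %in% names(plan$divergence)))
    r <- plan$divergence$rates
    stopifnot(all(c("pos1", "pos2", "pos3", "utr") %in% names(r)))
    if (any(r < 0)) stop("divergence rates must be >= 0")
    if (any(r > 0.75)) stop("divergence rate > 0.75: identity saturates")
  }
  invisible(TRUE)
}

.checkGaps <- function(spans, where) {
  if (is.null(spans) || nrow(spans) < 2L) return(invisible(TRUE))
  spans <- spans[order(spans[, 1L]), , drop = FALSE]
  gaps <- spans[-1L, 1L] - spans[-nrow(spans), 2L]
  if (any(gaps < .featureGap))
    stop("planted features in the ", where,
         " overlap or are closer than ", .featureGap, " nt")
  invisible(TRUE)
}

.randBases <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

## mutate one non-protected base of every spurious occurrence of the
## motifs until none remain; replacements are drawn from the target
## base distribution so scrubbing does not bias the G+C content
.scrubMotifs <- function(ch, motifs, allowedStarts, protected, gc = 0.5) {
  bases <- c("G", "C", "A", "T")
  probs <- c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)
  for (iter in 1:40) {
    s <- paste(ch, collapse = "")
    dirty <- FALSE
    for (motif in motifs) {
      hits <- setdiff(.motifHits(s, motif), allowedStarts[[motif]])
      for (h in hits) {
        span <- h:(h + nchar(motif) - 1L)
        mutable <- span[!protected[span]]
        if (!length(mutable))
          stop("cannot scrub spurious '", motif, "' at ", h,
               ": all bases protected")
        tgt <- mutable[length(mutable)]
        keep <- bases != ch[tgt]
        ch[tgt] <- sample(bases[keep], 1L, prob = probs[keep])
        dirty <- TRUE
      }
      if (dirty) break  # rescan from scratch after any edit
    }
    if (!dirty) return(ch)
  }
  stop("motif scrubbing did not converge")
}

.senseCodonsNoT <- function() {
  b <- c("A", "C", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

## break every spurious seed match (default 8/1/1 tolerance) by mutating
## background bases to ones that neither Watson-Crick- nor wobble-pair
## with the corresponding seed base; prefers the position-1 pair, whose
## violation alone disqualifies a site
.scrubSeedSites <- function(ch, truthSites, protected) {
  changed <- FALSE
  for (iter in 1:40) {
    s <- paste(ch, collapse = "")
    dirty <- FALSE
    for (mir in unique(truthSites$mirna)) {
      hits <- findSeedMatches(mir, s)$site_start
      spur <- setdiff(hits, truthSites$site_start[truthSites$mirna == mir])
      if (!length(spur)) next
      h <- spur[1L]
      span <- h:(h + 7L)
      mutable <- span[!protected[span]]
      if (!length(mutable))
        stop("cannot scrub spurious seed site at ", h)
      tgt <- if ((h + 7L) %in% mutable) h + 7L else mutable[length(mutable)]
      seedBase <- substr(mir, 9L - (tgt - h + 1L), 9L - (tgt - h + 1L))
      seedBase <- chartr("U", "T", toupper(seedBase))
      safe <- switch(seedBase, A = c("C", "A", "G"), C = c("C", "A", "T"),
                     G = c("A", "G"), T = c("C", "T"))
      ch[tgt] <- setdiff(safe, ch[tgt])[1L]
      changed <- TRUE; dirty <- TRUE
      break
    }
    if (!dirty) return(list(ch = ch, changed = changed))
  }
  stop("seed-site scrubbing did not converge")
}

#' Simulate one gene's UTRs and CDS with planted features
#'
#' The 5' UTR background is free of AUGs and the 3' UTR background is
#' free of polyadenylation hexamers and planted seed sites except
#' where the plan plants them, so every planted feature is recovered
#' by the corresponding scanner at its exact coordinates. uORF peptide
#' codons are drawn from T-free codons, which excludes both in-frame
#' stops and internal AUGs by construction. The CDS starts with ATG,
#' ends with a stop and contains no internal stop.
#'
#' @param plan A \code{\link{simulationPlan}}.
#' @param geneIndex 1-based gene index (selects the derived random
#'   substream).
#' @param variantIndex 1-based variant index.
#' @return A list with \code{gene}, \code{variant}, \code{utr5},
#'   \code{utr3}, \code{cds} (character sequences) and \code{truth}, a
#'   list of data.frames (\code{uorfs}, \code{pas}, \code{kmers},
#'   \code{mirna_sites}) recording every planted feature.
#' @export
simulateGene <- function(plan, geneIndex, variantIndex = 1L) {
  stopifnot(inherits(plan, "SimulationPlan"))
  .validatePlan(plan)
  ## scrubbing can (rarely) corner itself when a spurious motif falls
  ## entirely inside planted, protected bases; a fresh deterministic
  ## substream is drawn instead of giving up
  for (attempt in 1:20) {
    res <- tryCatch(
      .generateGene(plan, geneIndex, variantIndex, attempt),
      error = function(e) {
        if (grepl("scrub", conditionMessage(e))) NULL else stop(e)
      })
    if (!is.null(res)) return(res)
  }
  stop("could not generate a conflict-free gene after 20 attempts; ",
       "the plan leaves too little background sequence")
}

.generateGene <- function(plan, geneIndex, variantIndex, attempt) {
  sub <- .deriveSeed(plan$seed,
                     (geneIndex - 1L) * 100000L + variantIndex * 1000L +
                       attempt)
  .withSeed(sub, {
    gene <- sprintf("GENE%03d", geneIndex)
    variant <- letters[variantIndex]

    ## ---- 5' UTR ----
    L5 <- plan$utr5Length
    ch5 <- .randBases(L5, plan$gcTarget)
    protected5 <- rep(FALSE, L5)
    truth_uorfs <- NULL
    if (!is.null(plan$plantedUorfs)) {
      u <- plan$plantedUorfs[order(plan$plantedUorfs$cap_distance), ,
                             drop = FALSE]
      for (r in seq_len(nrow(u))) {
        cd <- u$cap_distance[r]; pep <- u$peptide_length[r]
        ctx <- u$context_class[r]
        start <- cd + 1L
        nPep <- pep - 1L  # codons after the ATG, before the stop
        pepPool <- .senseCodonsNoT()
        firstPool <- switch(ctx,
          optimal = pepPool[substr(pepPool, 1L, 1L) == "G"],
          pepPool[substr(pepPool, 1L, 1L) != "G"])
        pepCodons <- if (nPep > 0L)
          c(sample(firstPool, 1L),
            if (nPep > 1L) sample(pepPool, nPep - 1L, replace = TRUE))
        else character(0)
        orf <- paste0("ATG", paste(pepCodons, collapse = ""), "TAA")
        stop_end <- start + nchar(orf) - 1L
        ch5[start:stop_end] <- .seqChars(orf)
        if (cd >= 3L) {
          ch5[cd - 2L] <- if (ctx == "weak") "C" else "A"
          protected5[cd - 2L] <- TRUE
        }
        protected5[start:stop_end] <- TRUE
        truth_uorfs <- rbind(truth_uorfs, data.frame(
          start = start, stop_end = stop_end, cap_distance = cd,
          peptide_length = pep, context_class = ctx,
          distance_class = if (cd > 19L) "optimal"
                           else if (cd < 12L) "weak" else "intermediate"))
      }
    }
    truth_kmers <- NULL
    if (!is.null(plan$plantedKmers)) {
      cursor <- if (any(protected5)) max(which(protected5)) + .featureGap + 1L
                else 1L
      for (r in seq_len(nrow(plan$plantedKmers))) {
        km <- toupper(plan$plantedKmers$kmer[r])
        for (cp in seq_len(plan$plantedKmers$copies[r])) {
          w <- nchar(km)
          if (cursor + w - 1L > L5) stop("k-mer planting overflow")
          ch5[cursor:(cursor + w - 1L)] <- .seqChars(km)
          protected5[cursor:(cursor + w - 1L)] <- TRUE
          truth_kmers <- rbind(truth_kmers,
                               data.frame(kmer = km, position = cursor))
          cursor <- cursor + w + .featureGap
        }
      }
    }
    allowed5 <- list(ATG = if (is.null(truth_uorfs)) integer(0)
                           else truth_uorfs$start)
    kmotifs <- unique(truth_kmers$kmer)
    for (km in kmotifs)
      allowed5[[km]] <- truth_kmers$position[truth_kmers$kmer == km]
    ## two-strand counting merges a word with its reverse complement, so
    ## spurious reverse-complement occurrences are scrubbed too
    krc <- setdiff(vapply(kmotifs, .revcomp, character(1)), kmotifs)
    for (km in krc) allowed5[[km]] <- integer(0)
    ch5 <- .scrubMotifs(ch5, c("ATG", kmotifs, krc), allowed5, protected5,
                       gc = plan$gcTarget)
    utr5 <- paste(ch5, collapse = "")

    ## ---- 3' UTR ----
    L3 <- plan$utr3Length
    ch3 <- .randBases(L3, plan$gcTarget)
    protected3 <- rep(FALSE, L3)
    truth_pas <- NULL
    if (!is.null(plan$plantedPas)) {
      p <- plan$plantedPas
      for (r in seq_len(nrow(p))) {
        hex <- toupper(chartr("U", "T", p$hexamer[r]))
        pos <- L3 - p$distance_to_end[r]
        ch3[pos:(pos + 5L)] <- .seqChars(hex)
        protected3[pos:(pos + 5L)] <- TRUE
        type <- if (hex == "AATAAA") "C" else if (hex == "ATTAAA") "NC"
                else "NC_star"
        truth_pas <- rbind(truth_pas, data.frame(
          position = pos, hexamer = hex, pas_type = type,
          distance_to_end = p$distance_to_end[r]))
      }
    }
    truth_sites <- NULL
    if (!is.null(plan$plantedMirnaSites)) {
      m <- plan$plantedMirnaSites
      for (r in seq_len(nrow(m))) {
        mir <- toupper(chartr("U", "T", m$mirna[r]))
        site <- .revcomp(substr(mir, 1L, 8L))
        st <- m$site_start[r]
        ch3[st:(st + 7L)] <- .seqChars(site)
        protected3[st:(st + 7L)] <- TRUE
        truth_sites <- rbind(truth_sites, data.frame(
          mirna = mir, site = site, site_start = st, site_end = st + 7L))
      }
    }
    pasMotifs <- c("AATAAA", "ATTAAA", pasVariantHexamers())
    allowed3 <- setNames(vector("list", length(pasMotifs)), pasMotifs)
    for (mm in pasMotifs)
      allowed3[[mm]] <- if (is.null(truth_pas)) integer(0)
                        else truth_pas$position[truth_pas$hexamer == mm]
    siteMotifs <- unique(truth_sites$site)
    for (mm in siteMotifs)
      allowed3[[mm]] <- truth_sites$site_start[truth_sites$site == mm]
    ## exact-motif and near-match scrubs can feed each other, so
    ## alternate until a full pass changes nothing
    for (pass in 1:10) {
      ch3 <- .scrubMotifs(ch3, c(pasMotifs, siteMotifs), allowed3,
                          protected3, gc = plan$gcTarget)
      if (is.null(truth_sites)) break
      res <- .scrubSeedSites(ch3, truth_sites, protected3)
      ch3 <- res$ch
      if (!res$changed) break
    }
    utr3 <- paste(ch3, collapse = "")

    ## ---- CDS ----
    sense <- setdiff(names(Biostrings::GENETIC_CODE)
                     [Biostrings::GENETIC_CODE != "*"], character(0))
    body <- sample(sense, plan$cdsCodons - 2L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")

    list(gene = gene, variant = variant, utr5 = utr5, utr3 = utr3,
         cds = cds,
         truth = list(uorfs = truth_uorfs, pas = truth_pas,
                      kmers = truth_kmers, mirna_sites = truth_sites))
  })
}

#' Simulate a whole catalog from a plan
#'
#' @param plan A \code{\link{simulationPlan}}.
#' @return A list with \code{catalog} (a \linkS4class{UtrCatalog}
#'   holding the 5' UTR, 3' UTR and CDS records of every gene/variant)
#'   and \code{truth} (a list keyed "gene|variant" of per-gene truth
#'   lists).
#' @export
simulateCatalog <- function(plan) {
  stopifnot(inherits(plan, "SimulationPlan"))
  seqs <- character(0); gene <- character(0); variant <- character(0)
  region <- character(0); truth <- list()
  for (g in seq_len(plan$nGenes)) {
    for (v in seq_len(plan$variantsPerGene)) {
      sim <- simulateGene(plan, g, v)
      seqs <- c(seqs, sim$utr5, sim$utr3, sim$cds)
      gene <- c(gene, rep(sim$gene, 3L))
      variant <- c(variant, rep(sim$variant, 3L))
      region <- c(region, c("five_prime", "three_prime", "cds"))
      truth[[paste(sim$gene, sim$variant, sep = "|")]] <- sim$truth
    }
  }
  list(catalog = UtrCatalog(seqs, gene = gene, variant = variant,
                            species = plan$species, region = region),
       truth = truth)
}

#' Diverge a root gene into an ortholog family
#'
#' Each species' sequences are derived independently from the root by
#' per-site substitution: UTR sites mutate at the \code{utr} rate and
#' CDS sites at their codon-position rate (third position typically
#' fastest). A substituted base is replaced by one of the three other
#' bases uniformly (Jukes-Cantor style). CDS substitutions at codon
#' positions 1-2 that would create an internal stop codon are
#' reverted.
#'
#' @param records List with \code{utr5}, \code{utr3}, \code{cds}
#'   character sequences (e.g. from \code{\link{simulateGene}}).
#' @param rates Named vector \code{c(pos1, pos2, pos3, utr)} of
#'   per-site substitution probabilities, each in [0, 0.75].
#' @param species Character vector of species labels.
#' @param seed Integer seed.
#' @return A list with \code{utr5}, \code{utr3}, \code{cds} (named
#'   character vectors over species, root included as
#'   \code{"root"}) and \code{truth} (data.frame of realized
#'   substitution counts per species and site class).
#' @export
divergeFamily <- function(records, rates, species, seed = 1L) {
  stopifnot(all(c("pos1", "pos2", "pos3", "utr") %in% names(rates)))
  if (any(rates < 0)) stop("rates must be >= 0")
  if (any(rates > 0.75)) stop("rate > 0.75: identity saturates")
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  out5 <- c(root = records$utr5)
  out3 <- c(root = records$utr3)
  outc <- c(root = records$cds)
  truth <- NULL
  for (si in seq_along(species)) {
    sp <- species[si]
    .withSeed(.deriveSeed(seed, si), {
      mutateFlat <- function(s, rate) {
        ch <- .seqChars(s)
        hit <- runif(length(ch)) < rate
        for (i in which(hit))
          ch[i] <- sample(setdiff(bases, ch[i]), 1L)
        list(seq = paste(ch, collapse = ""), n = sum(hit))
      }
      m5 <- mutateFlat(records$utr5, rates[["utr"]])
      m3 <- mutateFlat(records$utr3, rates[["utr"]])
      ch <- .seqChars(records$cds)
      ncod <- length(ch) %/% 3L
      posRate <- rep(c(rates[["pos1"]], rates[["pos2"]], rates[["pos3"]]),
                     ncod)
      hit <- runif(length(ch)) < posRate
      nsub <- c(pos1 = 0L, pos2 = 0L, pos3 = 0L)
      for (i in which(hit)) {
        old <- ch[i]
        ch[i] <- sample(setdiff(bases, old), 1L)
        cod0 <- (i - 1L) %/% 3L + 1L
        codon <- paste(ch[(3L * cod0 - 2L):(3L * cod0)], collapse = "")
        internal <- cod0 < ncod
        if (internal && code[[codon]] == "*") {
          ch[i] <- old  # would create an internal stop
        } else {
          p <- (i - 1L) %% 3L + 1L
          nsub[p] <- nsub[p] + 1L
        }
      }
      out5[sp] <- m5$seq
      out3[sp] <- m3$seq
      outc[sp] <- paste(ch, collapse = "")
      truth <- rbind(truth, data.frame(
        species = sp,
        utr_subs = m5$n + m3$n, utr_sites = nchar(records$utr5) +
          nchar(records$utr3),
        pos1_subs = nsub[["pos1"]], pos2_subs = nsub[["pos2"]],
        pos3_subs = nsub[["pos3"]], cds_codons = ncod))
    })
  }
  list(utr5 = out5, utr3 = out3, cds = outc, truth = truth)
}
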