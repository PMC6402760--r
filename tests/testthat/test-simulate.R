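demoPlan <- function(seed = 7) simulationPlan(
  seed = seed, nGenes = 3,
  plantedUorfs = data.frame(cap_distance = c(25, 60),
                            context_class = c("optimal", "weak"),
                            peptide_length = c(5, 3)),
  plantedPas = data.frame(hexamer = c("AATAAA", "ATTAAA"),
                          distance_to_end = c(23, 120)),
  plantedKmers = data.frame(kmer = "CTGGCA", copies = 3),
  plantedMirnaSites = data.frame(mirna = "TGAGGTAGTAGGTTGTATAGTT",
                                 site_start = 50))

test_that("plans are validated up front", {
  expect_error(simulationPlan(plantedUorfs = data.frame(
    cap_distance = 25, context_class = "optimal", peptide_length = 1)),
    "peptide_length >= 2")
  expect_error(simulationPlan(plantedUorfs = data.frame(
    cap_distance = 1, context_class = "adequate", peptide_length = 3)),
    "cap_distance >= 3")
  expect_error(simulationPlan(utr5Length = 30, plantedUorfs = data.frame(
    cap_distance = 25, context_class = "weak", peptide_length = 5)),
    "exceeds")
  expect_error(simulationPlan(plantedPas = data.frame(
    hexamer = "AATAAA", distance_to_end = 400), utr3Length = 300),
    "does not fit")
  expect_error(simulationPlan(plantedUorfs = data.frame(
    cap_distance = c(20, 22), context_class = "weak", peptide_length = 1)),
    "overlap")
  expect_error(simulationPlan(plantedKmers = data.frame(
    kmer = "CATGCA", copies = 1)), "ATG")
  expect_error(simulationPlan(divergence = list(
    rates = c(pos1 = 0.1, pos2 = 0.1, pos3 = 0.9, utr = 0.1),
    species = "x")), "saturates")
})

test_that("generation is deterministic and byte-identical per seed", {
  a <- simulateGene(demoPlan(), 1)
  b <- simulateGene(demoPlan(), 1)
  expect_identical(a, b)
  c2 <- simulateGene(demoPlan(seed = 8), 1)
  expect_false(identical(a$utr5, c2$utr5))
})

test_that("every planted feature is recovered exactly by its scanner", {
  plan <- demoPlan()
  for (g in 1:8) {
    sim <- simulateGene(plan, g)
    tr <- sim$truth

    u <- extractUorfs(sim$utr5)
    expect_equal(u$start, as.integer(tr$uorfs$start))
    expect_equal(u$stop_end, as.integer(tr$uorfs$stop_end))
    expect_equal(u$context_class, tr$uorfs$context_class)
    expect_equal(u$distance_class, tr$uorfs$distance_class)
    expect_equal(length(findUaugs(sim$utr5)), nrow(tr$uorfs))

    p <- scanPas(sim$utr3)
    expect_equal(sort(p$position), sort(as.integer(tr$pas$position)))
    expect_equal(p$pas_type[order(p$position)],
                 tr$pas$pas_type[order(tr$pas$position)])

    expect_equal(countKmers(sim$utr5, 6)[["CTGGCA"]], 3L)

    sm <- findSeedMatches(tr$mirna_sites$mirna[1], sim$utr3)
    expect_equal(sm$site_start, as.integer(tr$mirna_sites$site_start))
  }
})

test_that("planted classes map to scanner classifications by construction", {
  sim <- simulateGene(demoPlan(), 2)
  p <- scanPas(sim$utr3)
  ve <- p[p$distance_to_end == 23, ]
  expect_equal(ve$pas_type, "C")
  expect_equal(ve$efficiency, "VE")
  far <- p[p$distance_to_end == 120, ]
  expect_equal(far$efficiency, "LE")
})

test_that("background G+C tracks the target without scrubbing bias", {
  ## averaged over genes so that per-sequence sampling noise
  ## (sd ~ 2 points at 600 nt) does not swamp a real bias
  for (gc in c(0.35, 0.5, 0.65)) {
    plan <- simulationPlan(seed = 11, nGenes = 8, utr5Length = 600,
                           utr3Length = 600, gcTarget = gc)
    sims <- lapply(1:8, function(g) simulateGene(plan, g))
    gc5 <- mean(vapply(sims, function(s) gcContent(s$utr5)$gc_percent,
                       numeric(1)))
    gc3 <- mean(vapply(sims, function(s) gcContent(s$utr3)$gc_percent,
                       numeric(1)))
    expect_lt(abs(gc5 - 100 * gc), 2)
    expect_lt(abs(gc3 - 100 * gc), 2)
  }
})

test_that("the CDS is a clean open reading frame", {
  sim <- simulateGene(simulationPlan(seed = 2, cdsCodons = 80), 1)
  expect_equal(substr(sim$cds, 1, 3), "ATG")
  codons <- substring(sim$cds, seq(1, nchar(sim$cds), 3),
                      seq(3, nchar(sim$cds), 3))
  expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
  expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
})

test_that("divergence obeys rates, stays in frame and matches theory", {
  root <- simulateGene(simulationPlan(seed = 13, cdsCodons = 150,
                                      utr5Length = 500, utr3Length = 500), 1)
  ## zero rates: all species identical to the root
  still <- divergeFamily(root[c("utr5", "utr3", "cds")],
                         rates = c(pos1 = 0, pos2 = 0, pos3 = 0, utr = 0),
                         species = c("s1", "s2"), seed = 3)
  expect_equal(unname(still$utr5[["s1"]]), root$utr5)
  expect_equal(identityValues(distanceMatrix(still$utr5))[1, 2], 100)

  ## diverged CDS keeps no internal stops
  fam <- divergeFamily(root[c("utr5", "utr3", "cds")],
                       rates = c(pos1 = 0.15, pos2 = 0.15, pos3 = 0.4,
                                 utr = 0.45),
                       species = paste0("s", 1:4), seed = 17)
  for (sp in paste0("s", 1:4)) {
    codons <- substring(fam$cds[[sp]], seq(1, nchar(root$cds), 3),
                        seq(3, nchar(root$cds), 3))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }

  ## mean leaf-leaf UTR identity near the closed-form expectation
  ids <- identityValues(distanceMatrix(fam$utr5[-1]))
  offdiag <- ids[upper.tri(ids)]
  expect_lt(abs(mean(offdiag) - 100 * oracleLeafIdentity(0.45)), 5)

  expect_error(divergeFamily(root[c("utr5", "utr3", "cds")],
                             rates = c(pos1 = 0.8, pos2 = 0, pos3 = 0,
                                       utr = 0),
                             species = "x"), "saturates")
})

test_that("whole catalogs assemble with one record per gene/region", {
  sim <- simulateCatalog(simulationPlan(seed = 9, nGenes = 4,
                                        variantsPerGene = 2))
  expect_equal(length(sim$catalog), 4L * 2L * 3L)
  md <- catalogMeta(sim$catalog)
  expect_equal(sort(unique(md$region)), c("cds", "five_prime", "three_prime"))
  expect_equal(length(sim$truth), 8L)
})
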