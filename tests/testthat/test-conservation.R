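test_that("pairwise identity handles identical, mismatched and random pairs", {
  expect_equal(pairwiseIdentity("ACGT", "ACGT"), 100)
  expect_equal(pairwiseIdentity("ACGT", "ACGA"), 75)
  expect_equal(pairwiseIdentity("ACGTACGT", "ACGTACGT"), 100)
  ## symmetry
  set.seed(3)
  for (i in 1:10) {
    a <- randomSeq(sample(40:120, 1)); b <- randomSeq(sample(40:120, 1))
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
  }
})

test_that("identity of simulated 60%-identity pairs is recovered", {
  set.seed(1001)
  ids <- replicate(200, {
    a <- randomSeq(150)
    ch <- strsplit(a, "")[[1]]
    hit <- runif(150) < 0.4
    ch[hit] <- vapply(ch[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    pairwiseIdentity(a, paste(ch, collapse = ""))
  })
  expect_lt(abs(mean(ids) - 60), 2)
})

test_that("terminal gaps are excluded so end-truncated variants score high", {
  ## identical core, one sequence extended at both ends
  core <- "ACGTACGTACGTACGTACGTACGTACGTAGTTCAA"
  ext <- paste0("GGGGGG", core, "TTTTTT")
  expect_equal(pairwiseIdentity(core, ext), 100)
})

test_that("codon-partitioned identity separates positions 1+2 from 3", {
  a <- "ATGGCGAAA"
  b <- "ATGGCAAAG"  # 3rd positions differ in codons 2 and 3
  got <- codonPartitionIdentity(a, b)
  expect_equal(got[["id_pos12"]], 100)
  expect_equal(got[["id_pos3"]], 100 / 3)
  expect_equal(codonPartitionIdentity(a, a), c(id_pos12 = 100, id_pos3 = 100))
  expect_error(codonPartitionIdentity("ACGT", "ACGT"), "frame")
  ## gapped codons excluded pairwise
  expect_equal(codonPartitionIdentity("ATG---AAA", "ATGGCAAAA"),
               c(id_pos12 = 100, id_pos3 = 100))
})

test_that("faster third positions produce id_pos12 > id_pos3 in most replicates", {
  set.seed(2024)
  root <- simulateGene(simulationPlan(seed = 55, cdsCodons = 120), 1)
  wins <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    fam <- divergeFamily(root[c("utr5", "utr3", "cds")],
                         rates = c(pos1 = 0.1, pos2 = 0.1, pos3 = 0.3,
                                   utr = 0.2),
                         species = c("sp1", "sp2"), seed = 7000 + r)
    idc <- codonPartitionIdentity(fam$cds[["sp1"]], fam$cds[["sp2"]])
    if (idc[["id_pos12"]] > idc[["id_pos3"]]) wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.95)
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  same <- distanceMatrix(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                           c = "ACGTACGTAC"))
  v <- identityValues(same)
  expect_true(all(v == 100))
  expect_equal(rownames(v), c("a", "b", "c"))

  dis <- distanceMatrix(c(x = strrep("AT", 20), y = strrep("GC", 20)))
  expect_lt(identityValues(dis)[1, 2], 30)
  expect_equal(identityValues(dis), t(identityValues(dis)))

  msa <- distanceMatrix(c(s1 = "ACGT-CGT", s2 = "ACGTACGT"),
                        mode = "msa_columns")
  expect_equal(identityMethod(msa), "msa_columns")
  expect_error(distanceMatrix(c(s1 = "ACGT", s2 = "ACGTA"),
                              mode = "msa_columns"), "equal length")
  expect_error(distanceMatrix("ACGT"), "at least 2")
})

test_that("homology calls use an inclusive 60% threshold", {
  expect_true(homologyCall(78.2))
  expect_false(homologyCall(45.6))
  expect_true(homologyCall(60))
  expect_false(homologyCall(59.999))
  expect_error(homologyCall(120), "0, 100")
})

test_that("NG86 reproduces the hand-worked example and degenerate cases", {
  same <- kaksNG86("GTTGTTGTT", "GTTGTTGTT")
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(same$undefined)
  expect_true(is.na(same$ratio))

  k <- kaksNG86("GTTGTTGTT", "GTAGTTGTT")
  expect_equal(k$sd, 1)
  expect_equal(k$nd, 0)
  expect_equal(k$s_sites, 3)
  expect_equal(k$n_sites, 6)
  expect_equal(k$ks, -0.75 * log(5 / 9))
  expect_equal(k$ka, 0)
  expect_equal(k$ratio, 0)
  expect_equal(k$n_sites + k$s_sites, 3 * k$codons)

  ## saturation flagged, not thrown
  sat <- kaksNG86("TTTTTTTTTTTT", "AAAAAAGGGGGG")
  expect_true(sat$undefined)
})

test_that("NG86 equals the exhaustive-pathway oracle on random codon pairs", {
  set.seed(90)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  for (i in 1:150) {
    ncod <- sample(1:3, 1)
    repeat {
      a <- paste(sample(bases, 3 * ncod, replace = TRUE), collapse = "")
      b <- paste(sample(bases, 3 * ncod, replace = TRUE), collapse = "")
      acod <- substring(a, seq(1, 3 * ncod, 3), seq(3, 3 * ncod, 3))
      bcod <- substring(b, seq(1, 3 * ncod, 3), seq(3, 3 * ncod, 3))
      if (!any(c(acod, bcod) %in% stops)) break
    }
    got <- kaksNG86(a, b)
    want <- oracleKaKs(a, b)
    expect_equal(got$nd, want$nd)
    expect_equal(got$sd, want$sd)
    expect_equal(got$n_sites, want$n_sites)
    expect_equal(got$s_sites, want$s_sites)
    expect_equal(got$ka, want$ka)
    expect_equal(got$ks, want$ks)
    ## symmetry in the two sequences
    rev <- kaksNG86(b, a)
    expect_equal(rev$ka, got$ka)
    expect_equal(rev$ks, got$ks)
  }
})
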