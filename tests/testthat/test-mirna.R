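let7 <- "TGAGGTAGTAGGTTGTATAGTT"

test_that("seed matching finds perfect, wobble and no-match cases", {
  ## perfect 8-mer seed complement
  hit <- findSeedMatches(let7, "GGGCTACCTCAGGG")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$site_start, 4L)
  expect_equal(hit$site_end, 11L)
  expect_equal(hit$n_gu, 0L)
  expect_equal(hit$n_mismatch, 0L)

  ## C -> T at an internal seed position creates a single G:U wobble
  hit2 <- findSeedMatches(let7, "GGGTTACCTCAGGG")
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$n_gu, 1L)
  expect_equal(hit2$n_mismatch, 0L)

  ## all-A UTR vs all-A miRNA cannot pair
  expect_equal(nrow(findSeedMatches("AAAAAAAAAA", "AAAAAAAAAAAA")), 0L)

  ## the position-1 pair must be Watson-Crick: breaking the 3'-most
  ## site base (which pairs miRNA position 1) kills the site even
  ## though the mismatch budget is not exhausted
  expect_equal(nrow(findSeedMatches(let7, "GGGCTACCTCTGGG")), 0L)

  expect_error(findSeedMatches(let7, "ACGTACGT", minSeed = 5), ">= 6")
})

test_that("ddG arithmetic and thresholds are exact on the stub engine", {
  cand <- findSeedMatches(let7, "GGGCTACCTCAGGG")
  very <- scoreSites(cand, "GGGCTACCTCAGGG", let7, stubEnergyEngine(-22, -5))
  expect_equal(very$ddg, -17)
  expect_equal(very$access_class, "very_accessible")

  inac <- scoreSites(cand, "GGGCTACCTCAGGG", let7, stubEnergyEngine(-12, -11))
  expect_equal(inac$ddg, -1)
  expect_equal(inac$access_class, "inaccessible")

  acc <- scoreSites(cand, "GGGCTACCTCAGGG", let7, stubEnergyEngine(-25, -12))
  expect_equal(acc$ddg, -13)
  expect_equal(acc$access_class, "accessible")

  ## boundary: ddg exactly -10 is not accessible (strict <)
  bd <- scoreSites(cand, "GGGCTACCTCAGGG", let7, stubEnergyEngine(-10, 0))
  expect_equal(bd$access_class, "inaccessible")

  ## rescoring is idempotent
  again <- scoreSites(very, "GGGCTACCTCAGGG", let7, stubEnergyEngine(-22, -5))
  expect_equal(as.data.frame(again), as.data.frame(very))
})

test_that("target counts keep very accessible a subset of accessible", {
  none <- S4Vectors::DataFrame(access_class = character(0))
  expect_equal(classifyTargets(none),
               c(n_accessible = 0L, n_very_accessible = 0L))
  one <- S4Vectors::DataFrame(access_class = "very_accessible")
  expect_equal(classifyTargets(one),
               c(n_accessible = 1L, n_very_accessible = 1L))
  mix <- S4Vectors::DataFrame(access_class = c("accessible", "accessible",
                                               "very_accessible",
                                               "inaccessible"))
  expect_equal(classifyTargets(mix),
               c(n_accessible = 3L, n_very_accessible = 1L))

  ## property under random stub energies
  set.seed(6)
  utr <- paste0(randomSeq(30), "CTACCTCA", randomSeq(30))
  cand <- findSeedMatches(let7, utr)
  for (i in 1:25) {
    eng <- stubEnergyEngine(runif(1, -30, 0), runif(1, -20, 0))
    cls <- classifyTargets(scoreSites(cand, utr, let7, eng))
    expect_lte(cls[["n_very_accessible"]], cls[["n_accessible"]])
  }
})

test_that("dg_open is never positive and reacts to structured flanks", {
  ## toy engine: unconstrained minus constrained ensemble energy <= 0
  utr_open <- paste0(strrep("A", 25), "CTACCTCA", strrep("A", 25))
  ## complementary flanks force a hairpin over the site
  utr_hairpin <- paste0(strrep("A", 10), "TGAGGTAGCC", "CTACCTCA",
                        strrep("A", 20))
  eng <- toyEnergyEngine()
  openSite <- scoreSites(findSeedMatches(let7, utr_open), utr_open, let7, eng)
  hpSite <- scoreSites(findSeedMatches(let7, utr_hairpin)[1, ],
                       utr_hairpin, let7, eng)
  expect_lte(openSite$dg_open[1], 0)
  expect_lte(hpSite$dg_open[1], 0)
  ## pairing the site into a hairpin makes it costlier to open
  expect_lt(hpSite$dg_open[1], openSite$dg_open[1])
})

test_that("the ViennaRNA engine contract returns sane energies", {
  eng <- viennaEnergyEngine()
  d <- eng$duplexEnergy("GGGGGGGG", "CCCCCCCC")
  expect_lt(d, -5)
  seqw <- "GGGAGGGAAAACCCTCCCAAAACTACCTCA"
  e_un <- eng$ensembleEnergy(seqw)
  e_con <- eng$ensembleEnergy(seqw, unpaired = c(1, 8))
  expect_lte(e_un, e_con + 1e-6)  # constraint can only raise the energy
})
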