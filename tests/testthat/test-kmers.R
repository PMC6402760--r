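test_that("k-mer counting matches a sliding-window oracle and merges strands", {
  expect_equal(countKmers("AAAA", k = 4, twoStrand = FALSE),
               c(AAAA = 1L))
  one <- countKmers("CTGGCA", k = 6, twoStrand = FALSE)
  expect_equal(one, c(CTGGCA = 1L))
  merged <- countKmers("CTGGCA", k = 6, twoStrand = TRUE)
  expect_equal(merged, c(CTGGCA = 1L))  # keyed by smaller of CTGGCA/TGCCAG
  both <- countKmers(c("CTGGCA", "TGCCAG"), k = 6, twoStrand = TRUE)
  expect_equal(both, c(CTGGCA = 2L))

  set.seed(14)
  seqs <- replicate(10, randomSeq(sample(50:200, 1)))
  got <- countKmers(seqs, k = 6, twoStrand = FALSE)
  want <- oracleKmerCount(seqs, 6)
  expect_equal(got[sort(names(want))], want[sort(names(want))])
  ## one-strand counts sum to the number of window positions
  expect_equal(sum(got), sum(nchar(seqs) - 6 + 1))

  ## two-strand merge: count(key) = count(w) + count(rc(w))
  got2 <- countKmers(seqs, k = 6, twoStrand = TRUE)
  for (w in names(got2)[1:25]) {
    rc <- oracleRevcomp(w)
    expect_equal(got2[[w]],
                 sum(want[names(want) %in% unique(c(w, rc))]))
  }
  expect_error(countKmers("ACG", k = 6), "longer than every")
  expect_error(countKmers("ACGTACGT", k = 2), "between 4 and 10")
})

test_that("background probabilities and expected counts are coherent", {
  ## uniform order-0 background: every 6-mer has probability 4^-6
  unif <- markovBackground(c("ACGTACGTACGTACGTACGT"), order = 0,
                           pseudocount = 1e6)  # swamps the data: uniform
  p <- kmerProbability("AACGTC", unif)
  expect_equal(p, 4^-6, tolerance = 1e-4)
  expect_equal(expectedKmerCount("AACGTC", unif, 4^6, twoStrand = FALSE),
               1, tolerance = 1e-3)

  ## zero-probability transitions error with a smoothing hint
  gOnly <- markovBackground("GGGGGGGG", order = 0, pseudocount = 0)
  expect_error(kmerProbability("GAGGGG", gOnly), "pseudocount")

  ## Markov-1 expected counts track a Monte-Carlo mean
  set.seed(42)
  train <- randomSeq(20000, gc = 0.6)
  bg <- markovBackground(train, order = 1)
  w <- "CCGTGA"
  npos <- 500 - 6 + 1
  expect_mc <- mean(replicate(200, {
    s <- randomSeq(500, gc = 0.6)
    oracleMotifCount(s, w)
  }))
  expect_equal(expectedKmerCount(w, bg, npos, twoStrand = FALSE),
               expect_mc, tolerance = 0.12)
})

test_that("binomial significance matches an exact summation oracle", {
  n <- 2080L * 10L
  exp_ct <- 2.77
  res <- kmerSignificance(16L, exp_ct, nTests = 2080L, totalPositions = n)
  oracle_p <- sum(dbinom(16:n, n, exp_ct / n))
  expect_equal(res$p_value, oracle_p, tolerance = 1e-12)
  expect_equal(res$sig_index, -log10(2080 * oracle_p))

  ## observed 0: p = 1, sig index = -log10(nTests)
  res0 <- kmerSignificance(0L, 1, nTests = 100L, totalPositions = 1000L)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$sig_index, -2)

  ## observed at expectation with many tests: E > 1, negative index
  resA <- kmerSignificance(5L, 5, nTests = 4096L, totalPositions = 10000L)
  expect_lt(resA$sig_index, 0)

  ## monotonicity in p and in nTests
  p_seq <- kmerSignificance(c(10L, 12L, 14L), 5, 100L, 10000L)
  expect_true(all(diff(p_seq$p_value) < 0))
  expect_true(all(diff(p_seq$sig_index) > 0))
  expect_gt(kmerSignificance(10L, 5, 10L, 10000L)$sig_index,
            kmerSignificance(10L, 5, 1000L, 10000L)$sig_index)

  expect_error(kmerSignificance(-1L, 1, 1L, 10L), ">= 0")
})

test_that("a planted motif is recovered among the top-ranked words", {
  set.seed(1234)
  hits <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    seqs <- replicate(50, randomSeq(300, gc = 0.5))
    ## plant 20 copies of a fixed motif at random positions
    for (i in sample(50, 20))
      seqs[i] <- paste0(substr(seqs[i], 1, 100), "CTGGCA",
                        substr(seqs[i], 107, 300))
    enr <- kmerEnrichment(seqs, k = 6, order = 0)
    top3 <- head(enr$kmer, 3)
    if ("CTGGCA" %in% top3 &&
        enr$sig_index[enr$kmer == "CTGGCA"] > 0) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})
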