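test_that("uAUG scanning finds all overlapping ATGs in order", {
  expect_equal(findUaugs("CCATGCCATGCC"), c(3L, 8L))
  expect_equal(findUaugs("CCCCCC"), integer(0))
  expect_equal(findUaugs("ATGATGATG"), c(1L, 4L, 7L))
  ## matches a naive window oracle on random sequences
  set.seed(21)
  for (i in 1:20) {
    s <- randomSeq(sample(30:300, 1), gc = 0.4)
    naive <- which(vapply(1:(nchar(s) - 2), function(p)
      substr(s, p, p + 2) == "ATG", logical(1)))
    expect_equal(findUaugs(s), as.integer(naive))
  }
})

test_that("uORF extraction walks frames to the first in-frame stop", {
  u <- extractUorfs("AAATGAAATAGCC")
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 3L)
  expect_equal(u$stop_end, 11L)
  expect_equal(u$peptide_length, 2L)
  expect_equal(u$cap_distance, 2L)

  expect_equal(nrow(extractUorfs("AAATGAAAAA")), 0L)  # no in-frame stop
  over <- extractUorfs("AAATGAAAAA", requireStopInUtr = FALSE)
  expect_equal(nrow(over), 1L)
  expect_true(over$overlaps_cds)
  expect_true(is.na(over$stop_end))

  tiny <- extractUorfs("ATGTAA")
  expect_equal(tiny$cap_distance, 0L)
  expect_equal(tiny$peptide_length, 1L)
  expect_equal(nrow(extractUorfs("ATGTAA", minCodons = 2)), 0L)
})

test_that("uORF extraction ignores sequence downstream of the stop codon", {
  set.seed(8)
  for (i in 1:10) {
    s <- paste0(randomSeq(20, gc = 0.3), "ATGAAACCCTAG")
    ext <- paste0(s, randomSeq(50))
    a <- extractUorfs(s); b <- extractUorfs(ext)
    keep <- b$stop_end <= nchar(s)
    expect_equal(as.data.frame(a), as.data.frame(b[keep, ]))
  }
})

test_that("context and cap-distance classes follow the -3/+4 and 12/19 rules", {
  ## -3 = A and +4 = G: optimal
  u <- extractUorfs(paste0(strrep("C", 23), "ACC", "ATGGCGTAA", "CC"))
  expect_equal(u$context_minus3, "A")
  expect_equal(u$context_plus4, "G")
  expect_equal(u$context_class, "optimal")
  expect_equal(u$distance_class, "optimal")   # cap distance 26 > 19

  ## cap distance 2: weak distance, missing -3 counts against context
  u2 <- extractUorfs("CCATGGCGTAA")
  expect_equal(u2$cap_distance, 2L)
  expect_equal(u2$distance_class, "weak")
  expect_equal(u2$context_class, "adequate")  # +4 G only

  ## -3 = C, +4 = A at distance 25: distance optimal, context weak
  s <- paste0(paste(rep("G", 22), collapse = ""), "CGG", "ATGACGTAA")
  u3 <- extractUorfs(s)
  expect_equal(u3$cap_distance, 25L)
  expect_equal(u3$distance_class, "optimal")
  expect_equal(u3$context_class, "weak")

  ## intermediate band 12..19
  u4 <- extractUorfs(paste0(paste(rep("C", 15), collapse = ""), "ATGAAATAA"))
  expect_equal(u4$distance_class, "intermediate")

  expect_error(classifyUorfs(data.frame(start = 50L), "ACGTACGT"),
               "out of range")
})

test_that("n_uorf never exceeds n_uaug, on random and on published counts", {
  set.seed(31)
  for (i in 1:30) {
    s <- randomSeq(sample(50:400, 1), gc = runif(1, 0.3, 0.7))
    expect_lte(nrow(extractUorfs(s)), length(findUaugs(s)))
  }
  ref <- read.delim(system.file("extdata", "lipocalin_5utr_features.tsv",
                                package = "utrlens"))
  both <- !is.na(ref$n_uaug) & !is.na(ref$n_uorf)
  expect_true(all(ref$n_uorf[both] <= ref$n_uaug[both]))
})

test_that("translation class rule and O/W strings behave as documented", {
  expect_equal(assignTranslationClass(0, 54), "III")
  expect_equal(assignTranslationClass(1, 232), "I")
  expect_equal(assignTranslationClass(0, 40), "III")
  expect_equal(assignTranslationClass(0, 101), "I")
  expect_equal(assignTranslationClass(0, 80, mfePerNt = -0.6), "I")
  expect_equal(assignTranslationClass(0, 80, mfePerNt = -0.2), "III")

  prof <- translationProfile("CCATGGCGTAACCCCCCCCCCCCCCCCCCCCCCCCCATGAAATAACC")
  expect_equal(prof$n_uorf, 2L)
  expect_equal(prof$efficiency_string, "O1/W1")
  expect_equal(prof$cart_class, "I")
})

test_that("translation class surrogate tracks most published labels", {
  ref <- read.delim(system.file("extdata", "lipocalin_5utr_features.tsv",
                                package = "utrlens"))
  ok <- !is.na(ref$n_uorf)
  pred <- assignTranslationClass(ref$n_uorf[ok], ref$length[ok])
  agree <- mean(pred == ref$cart[ok])
  ## two documented exceptions (both mouse Rbp4 variants) disagree
  expect_gte(agree, 0.9)
  mism <- ref$utr[ok][pred != ref$cart[ok]]
  expect_true(all(grepl("Rbp4", mism)))
})

test_that("cap-distance histograms conserve counts and recover plantings", {
  h <- capDistanceHistogram(c(5), binWidth = 10)
  expect_equal(h$count[1], 1L)
  expect_equal(sum(capDistanceHistogram(numeric(0))$count), 0L)

  set.seed(5)
  dists <- sample(0:80, 100, replace = TRUE)
  h2 <- capDistanceHistogram(dists, binWidth = 10)
  expect_equal(sum(h2$count), 100L)
  expect_equal(h2$count[1], sum(dists < 10))
})
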