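test_that("weighted validation ratio reproduces the stratified arithmetic", {
  # two strata of sites found in >= 2 samples
  strata <- data.frame(population = c(3196, 8724),
                       positive = c(69, 52), tested = c(110, 215))
  expect_equal(round(100 * weighted_validation_ratio(strata), 1), 34.5)
  # single stratum reduces to the simple ratio
  expect_equal(weighted_validation_ratio(
    data.frame(population = 50, positive = 5, tested = 10)), 0.5)
  # precomputed ratios are accepted
  expect_equal(weighted_validation_ratio(
    data.frame(population = c(10, 30), ratio = c(0.2, 0.6))), 0.5)
  expect_error(weighted_validation_ratio(
    data.frame(label = "bad", population = 10, positive = 0, tested = 0)),
    "bad")
})

test_that("weighted ratio equals member-level enumeration on random strata", {
  set.seed(43)
  for (rep_i in 1:50) {
    g <- sample(2:6, 1)
    strata <- data.frame(population = sample(5:200, g, TRUE),
                         tested = sample(1:20, g, TRUE))
    strata$positive <- vapply(strata$tested, function(t)
      sample(0:t, 1), 1L)
    # oracle: assign every population member its stratum ratio, average
    members <- unlist(mapply(function(N, p, t) rep(p / t, N),
                             strata$population, strata$positive,
                             strata$tested))
    expect_equal(weighted_validation_ratio(strata), mean(members))
    # bounded by the extreme stratum ratios
    r <- strata$positive / strata$tested
    expect_gte(weighted_validation_ratio(strata), min(r))
    expect_lte(weighted_validation_ratio(strata), max(r))
  }
})

test_that("minimal false fraction rounds expected failures per stratum", {
  # 3160 sites failing at 25.5% plus 2630 assumed failing at 76.5%
  expect_equal(round(estimate_min_false_fraction(3160, 0.255, 2630, 0.765), 3),
               0.487)
  expect_equal(round(3160 * 0.255) + round(2630 * 0.765), 806 + 2012)
  expect_equal(estimate_min_false_fraction(100, 0, 50, 0), 0)
  expect_equal(estimate_min_false_fraction(100, 1, 50, 1), 1)
  # monotone in each rate
  set.seed(47)
  r <- sort(stats::runif(5))
  v1 <- vapply(r, function(x)
    estimate_min_false_fraction(500, x, 300, 0.5), 1)
  v2 <- vapply(r, function(x)
    estimate_min_false_fraction(500, 0.5, 300, x), 1)
  expect_true(all(diff(v1) >= 0))
  expect_true(all(diff(v2) >= 0))
})

test_that("odds ratios follow the 2x2 cross-product with guarded zeros", {
  r <- odds_ratio_enrichment(c(e1 = 10, e2 = 90),
                             c(e1 = 100, e2 = 900))
  expect_equal(r$odds_ratio, c(1, 1))  # a/b = c/d
  r <- odds_ratio_enrichment(c(e1 = 10, e2 = 90),
                             c(e1 = 1000, e2 = 99000))
  expect_equal(r$odds_ratio[r$element == "e1"], 11)
  r <- odds_ratio_enrichment(c(e1 = 0, e2 = 90),
                             c(e1 = 1000, e2 = 9000))
  expect_equal(r$odds_ratio[r$element == "e1"], 0)
  # b*c = 0: undefined flag, no infinity
  r <- odds_ratio_enrichment(c(e1 = 90, e2 = 0), c(e1 = 500, e2 = 500))
  expect_true(r$undefined[r$element == "e1"])
  expect_true(is.na(r$odds_ratio[r$element == "e1"]))
  # invariant under uniform background scaling
  s <- c(a = 12, b = 30, c = 58)
  bg <- c(a = 400, b = 300, c = 300)
  expect_equal(odds_ratio_enrichment(s, bg)$odds_ratio,
               odds_ratio_enrichment(s, bg * 17)$odds_ratio)
})

test_that("motif profile measures strand-aware base fractions", {
  # genome crafted so every site reads 5'-CCCCT A GGGGG-3' in site sense
  seqs <- Biostrings::DNAStringSet(c(
    c1 = paste0("TTTT", "CCCCTAGGGGG", "TTTT"),   # '+' site at 10
    c2 = paste0("AAAAA", "CCCCCTAGGGG", "AAAA"))) # '-' site at 11
  # c2 forward 6..16 = CCCCCTAGGGG; its reverse complement reads
  # CCCCT A GGGGG in site sense, same as the c1 window
  sites <- data.frame(chrom = c("c1", "c2"), pos = c(10L, 11L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  p <- motif_profile(sites, seqs, halfwidth = 5)
  expect_equal(p$n, 2L)
  expect_equal(unname(p$fractions["A", "0"]), 1)
  expect_equal(unname(p$fractions["U", "-1"]), 1)    # both have T/U at -1
  expect_equal(unname(p$fractions["G", "1"]), 1)
  expect_equal(unname(colSums(p$fractions)), rep(1, 11))

  # site whose strand base is not A is excluded with a warning
  bad <- rbind(sites, data.frame(chrom = "c1", pos = 9L, strand = "+"))
  expect_warning(p2 <- motif_profile(bad, seqs), "not A")
  expect_equal(p2$n, 2L)
  # site too close to the contig end is skipped with a warning
  edge <- rbind(sites, data.frame(chrom = "c1", pos = 2L, strand = "+"))
  expect_warning(p3 <- motif_profile(edge, seqs), "contig")
  expect_equal(p3$n, 2L)
})

test_that("motif differences are zero-sum per position", {
  seqs <- Biostrings::DNAStringSet(c(c1 = paste0(
    paste(rep("ACGT", 30), collapse = ""), "A",
    paste(rep("TGCA", 30), collapse = ""))))
  set.seed(53)
  pos_a <- seq(21, 60, by = 4)  # forward A positions in the ACGT tract
  s1 <- data.frame(chrom = "c1", pos = pos_a, strand = "+")
  s2 <- data.frame(chrom = "c1", pos = pos_a + 4L, strand = "+")
  p1 <- motif_profile(s1, seqs)
  p2 <- motif_profile(s2, seqs)
  d <- motif_difference(p1, p2)
  expect_equal(unname(colSums(d)), rep(0, 11))
  expect_equal(motif_difference(p1, p1),
               p1$fractions - p1$fractions)
  expect_error(motif_difference(p1, motif_profile(s1, seqs, halfwidth = 3)),
               "half-width")
})

test_that("editable background counts strand-resolved adenosines per class", {
  b <- make_toy_bundle()
  counts <- count_editable_background(b)
  expect_setequal(names(counts), c("CDS", "UTR5", "UTR3", "lncRNA_exon",
                                   "intron", "vlincRNA", "antisense_exon",
                                   "antisense_intron", "intergenic"))
  expect_true(all(counts >= 0))
  # spot-check one class by brute force: UTR5 of geneA is 1001-1200 on '+'
  # (geneB UTR5 5301-5500 on '-'), no repeats or low-mappability there
  seq_c1 <- as.character(b$genome[["c1"]])
  expected_utr5 <-
    sum(strsplit(substr(seq_c1, 1001, 1200), "")[[1]] == "A") +
    sum(strsplit(substr(seq_c1, 5301, 5500), "")[[1]] == "T")
  expect_equal(unname(counts["UTR5"]), expected_utr5)
})
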