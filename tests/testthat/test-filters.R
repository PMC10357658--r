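test_that("variant filter removes exact position matches, strand-blind", {
  calls <- toy_calls(c(100, 100, 200), strand = c("+", "-", "+"))
  vars <- data.frame(chrom = "c1", pos = 100L)
  r <- filter_variants(calls, vars)
  expect_equal(r$removed$pos, c(100L, 100L))  # both strands removed
  expect_equal(r$pass$pos, 200L)
  # empty variant set keeps everything
  r0 <- filter_variants(calls, vars[0, ])
  expect_equal(nrow(r0$pass), 3L)
  expect_equal(nrow(r0$removed), 0L)
})

test_that("variant filter equals brute-force membership on random input", {
  set.seed(7)
  calls <- toy_calls(sample(1000, 1000, replace = TRUE),
                     strand = sample(c("+", "-"), 1000, TRUE),
                     chrom = sample(c("c1", "c2"), 1000, TRUE))
  vars <- data.frame(chrom = sample(c("c1", "c2"), 100, TRUE),
                     pos = sample(1000, 100, replace = TRUE))
  r <- filter_variants(calls, vars)
  oracle <- vapply(seq_len(nrow(calls)), function(i)
    any(vars$chrom == calls$chrom[i] & vars$pos == calls$pos[i]), TRUE)
  expect_equal(nrow(r$removed), sum(oracle))
  expect_setequal(site_keys(r$removed), site_keys(calls[oracle, ]))
})

test_that("repeat filter respects BED half-open boundaries and Alu tally", {
  b <- make_toy_bundle()  # Alu repeat covers 1-based 501..700
  calls <- toy_calls(c(501, 700, 701, 500, 9100))
  r <- filter_repeats(calls, b$repeats)
  expect_setequal(r$removed$pos, c(501L, 700L, 9100L))
  expect_setequal(r$pass$pos, c(701L, 500L))
  expect_equal(r$alu_fraction_of_removed, 2 / 3)  # 9100 is in L1
  # no removals: Alu fraction is 0, not NaN
  r0 <- filter_repeats(toy_calls(3000), b$repeats)
  expect_equal(r0$alu_fraction_of_removed, 0)
})

test_that("repeat filter equals brute-force interval scan on random input", {
  set.seed(11)
  n_iv <- 60
  iv_start <- sort(sample(5000, n_iv))
  iv <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    iv_start, iv_start + sample(5:50, n_iv, TRUE)))
  iv$name <- sample(c("Alu", "L2"), n_iv, TRUE)
  calls <- toy_calls(sample(5100, 1000, replace = TRUE))
  r <- filter_repeats(calls, iv)
  oracle <- vapply(calls$pos, function(p)
    any(GenomicRanges::start(iv) <= p & p <= GenomicRanges::end(iv)), TRUE)
  expect_equal(sort(r$removed$pos), sort(calls$pos[oracle]))
  expect_equal(sort(r$pass$pos), sort(calls$pos[!oracle]))
})

test_that("mappability filter enforces score-1 and strict window mean", {
  rle1 <- function(x) S4Vectors::Rle(x)
  cfg <- pipeline_config()
  # map100 = 1, map24 = 0.6 everywhere: kept
  tr100 <- list(c1 = rle1(rep(1, 1000)))
  tr24 <- list(c1 = rle1(rep(0.6, 1000)))
  r <- filter_mappability(toy_calls(500), tr100, tr24, cfg)
  expect_equal(nrow(r$pass), 1L)
  # map24 = 0.5 exactly: removed (strict inequality)
  r <- filter_mappability(toy_calls(500), tr100,
                          list(c1 = rle1(rep(0.5, 1000))), cfg)
  expect_equal(nrow(r$pass), 0L)
  # map100 = 0.999999 (text round-trip of 1) still counts as 1
  r <- filter_mappability(toy_calls(500),
                          list(c1 = rle1(rep(1 - 1e-12, 1000))), tr24, cfg)
  expect_equal(nrow(r$pass), 1L)
  # map100 < 1: removed even with perfect map24
  r <- filter_mappability(toy_calls(500),
                          list(c1 = rle1(rep(0.5, 1000))),
                          list(c1 = rle1(rep(1, 1000))), cfg)
  expect_equal(nrow(r$pass), 0L)
  # contig absent from tracks: removed with a warning
  expect_warning(
    r <- filter_mappability(toy_calls(500, chrom = "cX"), tr100, tr24, cfg),
    "absent")
  expect_equal(nrow(r$pass), 0L)
})

test_that("window mean near contig ends equals brute-force with zero fill", {
  set.seed(13)
  cfg <- pipeline_config()
  len <- 1000L
  for (rep_i in 1:25) {
    m24 <- round(stats::runif(len, 0.3, 1), 3)
    tr100 <- list(c1 = S4Vectors::Rle(rep(1, len)))
    tr24 <- list(c1 = S4Vectors::Rle(m24))
    pos <- sample(c(1:320, 680:1000, sample(len, 20)), 40)
    calls <- toy_calls(pos)
    r <- filter_mappability(calls, tr100, tr24, cfg)
    oracle_keep <- vapply(pos, function(p) {
      win <- (p - 150):(p + 150)
      vals <- ifelse(win >= 1 & win <= len, m24[pmax(pmin(win, len), 1)], 0)
      mean(vals) > 0.5
    }, TRUE)
    expect_setequal(site_keys(r$pass), site_keys(calls[oracle_keep, ]))
  }
})

test_that("filter order is fixed, tallies conserved, filters idempotent", {
  b <- make_toy_bundle()
  set.seed(17)
  calls <- toy_calls(sample(9999, 800, replace = TRUE),
                     strand = sample(c("+", "-"), 800, TRUE))
  calls <- rbind(calls, toy_calls(1234))  # sits on the known variant
  r <- filter_candidates(calls, b)
  rep_ <- r$report
  expect_equal(rep_$n_input,
               rep_$n_removed_variant + rep_$n_removed_repeat +
                 rep_$n_removed_mappability + rep_$n_pass)
  expect_gte(rep_$n_removed_variant, 1L)
  # each call lands in exactly one bin
  all_keys <- c(site_keys(r$pass), site_keys(r$removed$variant),
                site_keys(r$removed$repeat_),
                site_keys(r$removed$mappability))
  expect_equal(sort(all_keys), sort(site_keys(calls)))
  # idempotence: re-filtering the passing set removes nothing
  expect_equal(nrow(filter_variants(r$pass, b$variants)$removed), 0L)
  expect_equal(nrow(filter_repeats(r$pass, b$repeats)$removed), 0L)
  expect_equal(
    nrow(filter_mappability(r$pass, b$map100, b$map24)$removed), 0L)
})
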