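# small configuration for generator-only tests (the full default study is
# exercised in test-pipeline.R and test-acceptance.R via default_sim())
small_cfg <- function(...) {
  args <- list(genome_length = 2e5, n_genes = 10L, n_true_sites = 60L,
               n_samples = 4L, n_vlincs = 4L,
               fp_per_sample = c("REDItools" = 40L, "RED-ML" = 8L,
                                 "SPRINT" = 8L),
               hidden_snp_count = 4L, n_listed_variants = 12L,
               n_recurrent_fp = 5L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("the generator is deterministic: same seed, identical files", {
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  s1 <- simulate_editome(small_cfg(), d1)
  s2 <- simulate_editome(small_cfg(), d2)
  files <- c("genome.fa", "genes.gff3", "repeats.bed", "vlincs.bed",
             "variants.tsv", "map100.bedGraph", "map24.bedGraph",
             "db_sites.tsv", "truth_sites.tsv")
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  c1 <- sort(list.files(file.path(d1, "calls")))
  expect_identical(c1, sort(list.files(file.path(d2, "calls"))))
  for (f in c1)
    expect_identical(
      unname(tools::md5sum(file.path(d1, "calls", f))),
      unname(tools::md5sum(file.path(d2, "calls", f))), label = f)
  # different seed: different truth
  s3 <- simulate_editome(small_cfg(rng_seed = 99L), tempfile("sim3"))
  expect_false(identical(s1$truth$pos, s3$truth$pos))
})

test_that("planted truth sites are editable adenosines off repeats", {
  sim <- default_sim()$sim
  b <- default_sim()$bundle
  truth <- sim$truth
  # strand base is A at every truth site
  seqs <- lapply(b$genome, as.character)
  fwd <- mapply(function(ch, p) substr(seqs[[ch]], p, p),
                truth$chrom, truth$pos)
  expect_true(all(ifelse(truth$strand == "+", fwd == "A", fwd == "T")))
  # no truth site overlaps a repeat or a low-mappability position
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(truth$chrom,
                           IRanges::IRanges(truth$pos, width = 1)),
    b$repeats, ignore.strand = TRUE)
  expect_length(hits, 0L)
  m100 <- mapply(function(ch, p) as.numeric(b$map100[[ch]][p]),
                 truth$chrom, truth$pos)
  expect_true(all(m100 == 1))
  # truth context labels agree with the package's own classifier
  expect_equal(as.character(classify_context(truth, b)), truth$context)
  # annotated flag matches the emitted database
  expect_equal(match_annotated_db(truth, b$db_sites), truth$annotated)
})

test_that("truth U-at-minus-1 frequency recovers the configured probability", {
  fx <- default_sim()
  truth <- fx$sim$truth
  p <- motif_profile(truth, fx$bundle$genome)
  expect_equal(p$n, nrow(truth))
  ci <- binom_ci99(nrow(truth), fx$sim$config$p_u_minus1)
  u1 <- p$fractions["U", "-1"]
  expect_gte(u1, ci[1])
  expect_lte(u1, ci[2])
})

test_that("noise-free limit reproduces truth exactly in every sample", {
  cfg <- small_cfg(
    sensitivity = c("REDItools" = 1, "RED-ML" = 1, "SPRINT" = 1),
    fp_per_sample = c("REDItools" = 0L, "RED-ML" = 0L, "SPRINT" = 0L),
    n_recurrent_fp = 0L, hidden_snp_count = 0L, n_listed_variants = 0L)
  sim <- simulate_editome(cfg, tempfile("simclean"))
  calls <- read_calls_dir(sim$paths$calls_dir)
  tk <- site_keys(sim$truth)
  expect_setequal(unique(site_keys(calls)), tk)
  # every (site, sample, method) combination is present
  expect_equal(nrow(calls),
               nrow(sim$truth) * cfg$n_samples * 3L)
})

test_that("hidden SNPs are called everywhere at levels near one half", {
  fx <- default_sim()
  calls <- read_calls_dir(fx$sim$paths$calls_dir)
  hk <- site_keys(fx$sim$hidden_snps)
  sub <- calls[site_keys(calls) %in% hk, ]
  # all methods, all samples
  expect_equal(nrow(sub),
               nrow(fx$sim$hidden_snps) * fx$sim$config$n_samples * 3L)
  expect_true(all(abs(sub$editing_level - 0.5) < 0.2))
  # and none of them is in the emitted variant list
  expect_false(any(paste(fx$sim$hidden_snps$chrom, fx$sim$hidden_snps$pos)
                   %in% paste(fx$bundle$variants$chrom,
                              fx$bundle$variants$pos)))
})

test_that("per-method sensitivity is recovered from the call sets", {
  fx <- default_sim()
  calls <- read_calls_dir(fx$sim$paths$calls_dir)
  tk <- site_keys(fx$sim$truth)
  cfg <- fx$sim$config
  n_trials <- nrow(fx$sim$truth) * cfg$n_samples
  for (m in names(cfg$sensitivity)) {
    sub <- calls[calls$method_id == m & site_keys(calls) %in% tk, ]
    ci <- binom_ci99(n_trials, cfg$sensitivity[[m]])
    expect_gte(nrow(sub) / n_trials, ci[1])
    expect_lte(nrow(sub) / n_trials, ci[2])
  }
})

test_that("validation outcomes reflect ground truth and hidden SNPs", {
  fx <- default_sim()
  final <- fx$res$final
  val <- generate_validation_outcomes(final, fx$sim,
                                      path = tempfile(fileext = ".tsv"))
  tk <- site_keys(fx$sim$truth)
  hk <- site_keys(fx$sim$hidden_snps)
  vk <- site_keys(val)
  expect_equal(val$status[vk %in% tk], rep("validated", sum(vk %in% tk)))
  expect_equal(val$status[vk %in% hk],
               rep("sequence_variant", sum(vk %in% hk)))
  expect_true(all(val$status[!vk %in% c(tk, hk)] == "failed"))
  # adjacent-site fraction 0 means nothing is added downstream
  sim0 <- fx$sim
  sim0$config$adjacent_fraction <- 0
  val0 <- generate_validation_outcomes(final, sim0,
                                       path = tempfile(fileext = ".tsv"))
  expect_true(all(!nzchar(val0$adjacent)))
})
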