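test_that("read_method_calls ingests well-formed tables and rejects bad rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tstrand\tediting_level\tcoverage",
               "c1\t100\t+\t0.30\t25",
               "c1\t200\t-\t0.10\t12",
               "c2\t50\t+\t1.00\t7"), f)
  x <- read_method_calls(f, "s1", "REDItools")
  expect_equal(nrow(x), 3L)
  expect_equal(x$sample_id, rep("s1", 3))
  expect_equal(attr(x, "n_rejected"), 0L)

  # empty file with header
  writeLines("chrom\tpos\tstrand\tediting_level\tcoverage", f)
  expect_equal(nrow(read_method_calls(f, "s1", "SPRINT")), 0L)

  # out-of-range editing level is a record-level rejection
  writeLines(c("chrom\tpos\tstrand\tediting_level\tcoverage",
               "c1\t100\t+\t0.30\t25",
               "c1\t200\t+\t1.2\t12",
               "c1\t300\t-\t0.10\t9"), f)
  expect_message(x <- read_method_calls(f, "s1", "RED-ML"), "rejected")
  expect_equal(nrow(x), 2L)
  expect_equal(attr(x, "n_rejected"), 1L)

  # a missing column is a format error naming the column
  writeLines(c("chrom\tpos\tstrand\tcoverage", "c1\t100\t+\t25"), f)
  expect_error(read_method_calls(f, "s1", "RED-ML"), "editing_level")
  expect_error(read_method_calls(f, "s1", "not-a-caller"), "method_id")
})

test_that("site tables round-trip exactly through write and re-parse", {
  calls <- rbind(
    toy_calls(c(2000, 1100), sample_id = "s1", method_id = "RED-ML",
              level = c(1 / 3, 0.123456789012345)),
    toy_calls(c(2000, 9900), sample_id = "s2", method_id = "SPRINT",
              level = c(0.7, 0.25)))
  sites <- build_consensus(calls)
  sites$annotated <- c(TRUE, FALSE, FALSE)
  sites$context <- factor(c("CDS", "UTR5", "intergenic"),
                          levels = levels(classify_context(
                            toy_sites(1, "+"), make_toy_bundle())))
  sites$final <- TRUE
  f <- tempfile(fileext = ".tsv")
  write_site_table(sites, f)
  back <- read_site_table(f)
  for (col in c("chrom", "pos", "strand", "methods", "n_samples",
                "max_level", "annotated", "final"))
    expect_identical(back[[col]], sites[[col]], label = col)
  expect_identical(as.character(back$context), as.character(sites$context))

  # empty set: header-only file
  write_site_table(sites[0, ], f)
  expect_identical(length(readLines(f)), 1L)
  expect_equal(nrow(read_site_table(f)), 0L)
})

test_that("BED export uses 0-based half-open intervals and scaled scores", {
  sites <- toy_sites(c(100, 250), c("+", "-"))
  sites$max_level <- c(0.5, 0.221)
  f <- tempfile(fileext = ".bed")
  export_sites_bed(sites, f)
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(bed$V2, c(99, 249))
  expect_equal(bed$V3, c(100, 250))
  expect_equal(bed$V5, c(500, 221))
  expect_equal(bed$V6, c("+", "-"))
  # 1-based in, 0-based BED, 1-based re-import round-trips the coordinate
  gr <- rtracklayer::import(f)
  expect_equal(GenomicRanges::start(gr), sites$pos)
})

test_that("annotation bundle construction derives gene sub-intervals", {
  b <- make_toy_bundle()
  feats <- b$features
  ty <- as.character(feats$type)
  a <- feats[feats$tx_id == "geneA.t1"]
  expect_setequal(as.character(a$type)[as.character(a$type) != "exon"],
                  c("CDS", "UTR5", "UTR3", "intron"))
  utr5 <- a[a$type == "UTR5"]
  expect_equal(c(GenomicRanges::start(utr5), GenomicRanges::end(utr5)),
               c(1001, 1200))
  introns <- a[a$type == "intron"]
  expect_equal(GenomicRanges::start(introns), c(1401, 2301))
  expect_equal(GenomicRanges::end(introns), c(1900, 2800))

  # minus-strand gene: UTR5 is genomic-right of the CDS
  b_utr5 <- feats[feats$tx_id == "geneB.t1" & ty == "UTR5"]
  expect_equal(GenomicRanges::start(b_utr5), 5301)
  expect_equal(GenomicRanges::end(b_utr5), 5500)
  b_utr3 <- feats[feats$tx_id == "geneB.t1" & ty == "UTR3"]
  expect_equal(GenomicRanges::end(b_utr3), 4150)

  # transcript lacking CDS: exonic bases are non-coding exon
  c_feats <- feats[feats$tx_id == "geneC.t1"]
  expect_setequal(unique(as.character(c_feats$type)),
                  c("lncRNA_exon", "exon", "intron"))

  # exons and introns are disjoint and tile each transcript span
  for (id in unique(feats$tx_id)) {
    fx <- feats[feats$tx_id == id]
    ex <- fx[ty[feats$tx_id == id] == "exon"]
    intr <- fx[ty[feats$tx_id == id] == "intron"]
    expect_equal(length(GenomicRanges::intersect(ex, intr)), 0L)
    expect_equal(
      sum(GenomicRanges::width(GenomicRanges::reduce(
        c(ex, intr), ignore.strand = TRUE))),
      max(GenomicRanges::end(fx)) - min(GenomicRanges::start(fx)) + 1L)
  }
})

test_that("malformed annotation inputs are hard errors", {
  dir <- make_toy_dir()
  bad_bed <- file.path(dir, "bad.bed")
  writeLines("c1\t100\t100\tx\t0\t.", bad_bed)  # end <= start
  expect_error(
    read_annotation_bundle(
      file.path(dir, "genome.fa"), file.path(dir, "genes.gff3"),
      bad_bed, file.path(dir, "vlincs.bed"),
      file.path(dir, "variants.tsv"), file.path(dir, "map100.bedGraph"),
      file.path(dir, "map24.bedGraph"), file.path(dir, "db_sites.tsv")),
    "malformed|interval")

  bad_gff <- file.path(dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "cMISSING\ttoy\tgene\t1\t100\t.\t+\t.\tID=g1"), bad_gff)
  expect_error(
    read_annotation_bundle(
      file.path(dir, "genome.fa"), bad_gff,
      file.path(dir, "repeats.bed"), file.path(dir, "vlincs.bed"),
      file.path(dir, "variants.tsv"), file.path(dir, "map100.bedGraph"),
      file.path(dir, "map24.bedGraph"), file.path(dir, "db_sites.tsv")),
    "cMISSING")
})

test_that("mappability tracks default unrecorded positions to score 0", {
  f <- tempfile(fileext = ".bedGraph")
  writeLines("c1\t10\t20\t0.8", f)  # only 11-20 (1-based) recorded
  tr <- read_mappability_track(f, c(c1 = 50L))
  expect_equal(length(tr$c1), 50L)
  expect_equal(as.numeric(tr$c1[5]), 0)
  expect_equal(as.numeric(tr$c1[15]), 0.8)
  expect_equal(as.numeric(tr$c1[25]), 0)
})

test_that("validation records parse and enforce status consistency", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste("chrom", "pos", "strand", "tested_sample",
                     "rna_outcome", "gdna_outcome", "status", "adjacent",
                     sep = "\t"),
               "c1\t2000\t+\tS01\tedited\thomozygous_reference\tvalidated\tc1:2003:+,c1:1997:+",
               "c1\t2100\t-\tS02\tedited\tvariant\tsequence_variant\t",
               "c1\t2200\t+\tS03\tnot_detected\thomozygous_reference\tfailed\t"), f)
  v <- read_validation_records(f)
  expect_equal(v$status, c("validated", "sequence_variant", "failed"))
  expect_equal(nrow(v$adjacent[[1]]), 2L)
  expect_equal(v$adjacent[[1]]$pos, c(2003L, 1997L))
  expect_equal(nrow(v$adjacent[[2]]), 0L)

  writeLines(c(paste("chrom", "pos", "strand", "tested_sample",
                     "rna_outcome", "gdna_outcome", "status", "adjacent",
                     sep = "\t"),
               "c1\t2000\t+\tS01\tnot_detected\thomozygous_reference\tvalidated\t"),
             f)
  expect_error(read_validation_records(f), "inconsistent")
})
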