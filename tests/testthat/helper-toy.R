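# Toy annotation bundle with hand-laid-out gene models so expected context
# labels and filter outcomes can be derived by eye:
#
# contig c1, 10 kb
#   geneA  coding  '+'  1001-3000; exons 1001-1400, 1901-2300, 2801-3000
#                        CDS 1201-2900 (within exons); introns 1401-1900,
#                        2301-2800; UTR5 1001-1200; UTR3 2901-3000
#   geneB  coding  '-'  4001-5500; exons 4001-4300, 5001-5500;
#                        CDS 4151-5300; intron 4301-5000;
#                        UTR5 5301-5500; UTR3 4001-4150
#   geneC  lncRNA  '+'  6001-7000; exons 6001-6200, 6801-7000;
#                        intron 6201-6800
#   vlinc V1 '+' 7501-8800 (intergenic), V2 '+' 1350-2500 (overlaps geneA)
#   repeats: Alu 501-700, L1 8999-9200 (1-based inclusive)
#   map100: 1 everywhere except 9501-9600 (0)
#   map24 : 1 everywhere except 9401-9700 (0.2)
#   variants: c1:1234;  db sites: c1:2000:+ , c1:2100 (strandless)
make_toy_dir <- function(dir = tempfile("toybundle")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(42)
  seq_c1 <- paste0(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                   collapse = "")
  writeLines(c(">c1", seq_c1), file.path(dir, "genome.fa"))

  gff <- c("##gff-version 3",
    "c1\ttoy\tgene\t1001\t3000\t.\t+\t.\tID=geneA;gene_biotype=protein_coding",
    "c1\ttoy\ttranscript\t1001\t3000\t.\t+\t.\tID=geneA.t1;Parent=geneA;gene_biotype=protein_coding",
    "c1\ttoy\texon\t1001\t1400\t.\t+\t.\tParent=geneA.t1",
    "c1\ttoy\texon\t1901\t2300\t.\t+\t.\tParent=geneA.t1",
    "c1\ttoy\texon\t2801\t3000\t.\t+\t.\tParent=geneA.t1",
    "c1\ttoy\tCDS\t1201\t1400\t.\t+\t0\tParent=geneA.t1",
    "c1\ttoy\tCDS\t1901\t2300\t.\t+\t0\tParent=geneA.t1",
    "c1\ttoy\tCDS\t2801\t2900\t.\t+\t0\tParent=geneA.t1",
    "c1\ttoy\tgene\t4001\t5500\t.\t-\t.\tID=geneB;gene_biotype=protein_coding",
    "c1\ttoy\ttranscript\t4001\t5500\t.\t-\t.\tID=geneB.t1;Parent=geneB;gene_biotype=protein_coding",
    "c1\ttoy\texon\t4001\t4300\t.\t-\t.\tParent=geneB.t1",
    "c1\ttoy\texon\t5001\t5500\t.\t-\t.\tParent=geneB.t1",
    "c1\ttoy\tCDS\t4151\t4300\t.\t-\t0\tParent=geneB.t1",
    "c1\ttoy\tCDS\t5001\t5300\t.\t-\t0\tParent=geneB.t1",
    "c1\ttoy\tgene\t6001\t7000\t.\t+\t.\tID=geneC;gene_biotype=lncRNA",
    "c1\ttoy\ttranscript\t6001\t7000\t.\t+\t.\tID=geneC.t1;Parent=geneC;gene_biotype=lncRNA",
    "c1\ttoy\texon\t6001\t6200\t.\t+\t.\tParent=geneC.t1",
    "c1\ttoy\texon\t6801\t7000\t.\t+\t.\tParent=geneC.t1")
  writeLines(gff, file.path(dir, "genes.gff3"))

  writeLines(c("c1\t500\t700\tAlu\t0\t.",
               "c1\t8998\t9200\tL1\t0\t."),
             file.path(dir, "repeats.bed"))
  writeLines(c("c1\t7500\t8800\tV1\t0\t+",
               "c1\t1349\t2500\tV2\t0\t+"),
             file.path(dir, "vlincs.bed"))
  writeLines(c("chrom\tpos", "c1\t1234"), file.path(dir, "variants.tsv"))
  writeLines(c("c1\t0\t9500\t1", "c1\t9500\t9600\t0", "c1\t9600\t10000\t1"),
             file.path(dir, "map100.bedGraph"))
  writeLines(c("c1\t0\t9400\t1", "c1\t9400\t9700\t0.2",
               "c1\t9700\t10000\t1"),
             file.path(dir, "map24.bedGraph"))
  writeLines(c("chrom\tpos\tstrand", "c1\t2000\t+", "c1\t2100\t."),
             file.path(dir, "db_sites.tsv"))
  dir
}

make_toy_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- make_toy_dir()
      cache <<- read_annotation_bundle(
        file.path(dir, "genome.fa"), file.path(dir, "genes.gff3"),
        file.path(dir, "repeats.bed"), file.path(dir, "vlincs.bed"),
        file.path(dir, "variants.tsv"), file.path(dir, "map100.bedGraph"),
        file.path(dir, "map24.bedGraph"), file.path(dir, "db_sites.tsv"))
    }
    cache
  }
})

toy_sites <- function(pos, strand, chrom = "c1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             stringsAsFactors = FALSE)
}

toy_calls <- function(pos, strand = "+", sample_id = "s1",
                      method_id = "RED-ML", level = 0.5, coverage = 30L,
                      chrom = "c1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             editing_level = level, coverage = as.integer(coverage),
             sample_id = sample_id, method_id = method_id,
             stringsAsFactors = FALSE)
}

write_calls_tsv <- function(df, path) {
  utils::write.table(
    df[c("chrom", "pos", "strand", "editing_level", "coverage")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided binomial 99% acceptance band for an observed proportion
binom_ci99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p) / n
}
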