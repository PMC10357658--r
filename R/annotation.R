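#' Load the annotation bundle used by filtering and context classification
#'
#' Reads the genome, gene models, repeat and vlincRNA intervals, known
#' variant positions, the two alignability tracks and the annotated
#' editing-site database into one indexed object.  Gene models are
#' decomposed per transcript into CDS, 5'/3' UTR, non-coding exon and
#' intron intervals (strand-aware); alignability tracks are expanded to
#' per-position run-length vectors with positions missing from the
#' BedGraph treated as score 0, so that a site can only pass the
#' mappability filter where uniqueness was positively recorded.
#'
#' @param fasta Genome FASTA.
#' @param gff3 Gene models in GFF3 (`gene`/`transcript` or `mRNA`, `exon`,
#'   `CDS` features with `ID`/`Parent` attributes; transcript biotype read
#'   from a `gene_biotype` or `biotype` attribute, defaulting to
#'   `protein_coding` when a transcript has CDS and `lncRNA` otherwise).
#' @param repeats_bed BED of repeat intervals (name column = repeat family,
#'   e.g. `Alu`); strand is ignored.
#' @param vlincs_bed BED6 of stranded vlincRNA intervals.
#' @param variants Known variant positions: a 2-column TSV (`chrom`,
#'   `pos`, 1-based) or a VCF (`.vcf`/`.vcf.gz`, read via the
#'   VariantAnnotation package).
#' @param map100_bedgraph 100mer alignability BedGraph.
#' @param map24_bedgraph 24mer alignability BedGraph.
#' @param db_sites TSV of annotated editing-database sites: columns
#'   `chrom`, `pos`, and optionally `strand` (`.` or `NA` = strandless
#'   record).
#' @return A list of class `"annotation_bundle"` with elements `genome`
#'   (DNAStringSet), `seqlens`, `features` (GRanges with a `type` column
#'   over CDS/UTR5/UTR3/lncRNA_exon/exon/intron and `tx_id`), `repeats`,
#'   `vlincs` (GRanges), `variants` (data.frame `chrom`,`pos`), `map100`,
#'   `map24` (per-contig numeric Rle lists) and `db_sites` (data.frame).
#' @export
read_annotation_bundle <- function(fasta, gff3, repeats_bed, vlincs_bed,
                                   variants, map100_bedgraph,
                                   map24_bedgraph, db_sites) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))

  gff <- rtracklayer::import(gff3, format = "gff3")
  rpt <- .import_bed_checked(repeats_bed)
  vli <- .import_bed_checked(vlincs_bed)
  .check_contigs(c(as.character(GenomeInfoDb::seqlevels(gff)),
                   as.character(GenomeInfoDb::seqlevels(rpt)),
                   as.character(GenomeInfoDb::seqlevels(vli))),
                 names(genome))

  bundle <- list(
    genome = genome,
    seqlens = seqlens,
    features = derive_tx_features(gff),
    repeats = rpt,
    vlincs = vli,
    variants = read_variant_positions(variants),
    map100 = read_mappability_track(map100_bedgraph, seqlens),
    map24 = read_mappability_track(map24_bedgraph, seqlens),
    db_sites = read_db_sites(db_sites))
  class(bundle) <- "annotation_bundle"
  bundle
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("annotation bundle\n")
  cat(sprintf("  genome    : %d contig(s), %s bp\n", length(x$genome),
              format(sum(as.numeric(x$seqlens)), big.mark = ",")))
  cat(sprintf("  features  : %d intervals over %d transcript(s)\n",
              length(x$features),
              length(unique(x$features$tx_id))))
  cat(sprintf("  repeats   : %d intervals; vlincRNAs: %d\n",
              length(x$repeats), length(x$vlincs)))
  cat(sprintf("  variants  : %d positions; annotated DB sites: %d\n",
              nrow(x$variants), nrow(x$db_sites)))
  invisible(x)
}

.check_contigs <- function(used, known) {
  unknown <- setdiff(unique(used), known)
  if (length(unknown))
    stop("contig(s) present in annotation but absent from the genome ",
         "FASTA: ", paste(unknown, collapse = ", "), call. = FALSE)
}

.import_bed_checked <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   stop("malformed BED ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  if (length(gr) && any(GenomicRanges::width(gr) < 1L))
    stop("malformed BED ", path, ": interval with end <= start",
         call. = FALSE)
  gr
}

#' Decompose GFF3 gene models into classified transcript sub-intervals
#'
#' Per transcript: exons come from `exon` features; introns are the gaps
#' between exons inside the transcript span; coding transcripts (those
#' with `CDS` features) get their exonic bases split into CDS, 5' UTR
#' (exonic bases upstream of the CDS in transcript orientation) and 3' UTR
#' (downstream); transcripts without CDS contribute `lncRNA_exon`
#' intervals.  Plain `exon` intervals are retained for antisense lookups.
#'
#' @param gff A GRanges as returned by `rtracklayer::import(format="gff3")`.
#' @return GRanges with metadata columns `type` (one of `CDS`, `UTR5`,
#'   `UTR3`, `lncRNA_exon`, `exon`, `intron`) and `tx_id`.
#' @export
derive_tx_features <- function(gff) {
  empty <- function() {
    g <- GenomicRanges::GRanges()
    g$type <- character()
    g$tx_id <- character()
    g
  }
  type <- as.character(gff$type)
  tx <- gff[type %in% c("transcript", "mRNA", "lnc_RNA")]
  if (!length(tx)) return(empty())
  ex <- gff[type == "exon"]
  cds <- gff[type == "CDS"]
  parent1 <- function(g) {
    p <- g$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_,
           "")
  }
  tx_id <- as.character(tx$ID)
  tx_strand <- as.character(GenomicRanges::strand(tx))
  spans <- GenomicRanges::granges(tx)
  S4Vectors::mcols(spans) <- NULL
  GenomicRanges::strand(spans) <- "*"

  by_tx <- function(g, parent) {
    gg <- GenomicRanges::granges(g)
    GenomicRanges::strand(gg) <- "*"
    GenomicRanges::reduce(
      S4Vectors::split(gg, factor(parent, levels = tx_id)))
  }
  exl <- by_tx(ex, parent1(ex))
  no_exon <- S4Vectors::elementNROWS(exl) == 0L
  if (any(no_exon)) # transcript without exon lines: whole span is exonic
    exl[no_exon] <- methods::as(spans[no_exon], "GRangesList")
  intl <- GenomicRanges::psetdiff(spans, exl)
  cdsl <- by_tx(cds, parent1(cds))
  has_cds <- S4Vectors::elementNROWS(cdsl) > 0L

  # UTRs: exonic bases left/right of the CDS span, oriented by strand
  utr_left <- utr_right <- NULL
  if (any(has_cds)) {
    exc <- exl[has_cds]
    spc <- spans[has_cds]
    cds_lo <- min(GenomicRanges::start(cdsl[has_cds]))
    cds_hi <- max(GenomicRanges::end(cdsl[has_cds]))
    chrom <- as.character(GenomicRanges::seqnames(spc))
    left <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      GenomicRanges::start(spc), cds_lo - 1L))
    right <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      cds_hi + 1L, GenomicRanges::end(spc)))
    utr_left <- GenomicRanges::pintersect(exc, left)
    utr_right <- GenomicRanges::pintersect(exc, right)
  }

  collect <- function(gl, which_tx, ty) {
    if (is.null(gl)) return(NULL)
    g <- unlist(gl, use.names = FALSE)
    n <- S4Vectors::elementNROWS(gl)
    idx <- rep(which_tx, n)
    keep <- GenomicRanges::width(g) > 0L
    g <- g[keep]; idx <- idx[keep]
    if (!length(g)) return(NULL)
    S4Vectors::mcols(g) <- NULL
    GenomicRanges::strand(g) <- tx_strand[idx]
    g$type <- ty
    g$tx_id <- tx_id[idx]
    g
  }
  all_idx <- seq_along(tx)
  hc_idx <- all_idx[has_cds]
  plus <- tx_strand[has_cds] == "+"
  parts <- list(
    collect(cdsl[has_cds], hc_idx, "CDS"),
    collect(utr_left[plus], hc_idx[plus], "UTR5"),
    collect(utr_right[!plus], hc_idx[!plus], "UTR5"),
    collect(utr_right[plus], hc_idx[plus], "UTR3"),
    collect(utr_left[!plus], hc_idx[!plus], "UTR3"),
    collect(exl[!has_cds], all_idx[!has_cds], "lncRNA_exon"),
    collect(exl, all_idx, "exon"),
    collect(intl, all_idx, "intron"))
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) return(empty())
  suppressWarnings(do.call(c, parts))
}

#' Read known variant positions
#'
#' @param path A 2-column TSV (`chrom`, `pos`) or a VCF file.
#' @return Data.frame with columns `chrom` and `pos` (1-based).
#' @export
read_variant_positions <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading VCF variant lists requires the VariantAnnotation ",
           "package; supply a chrom/pos TSV instead", call. = FALSE)
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      stringsAsFactors = FALSE))
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(x)))
    stop("variant table lacks chrom/pos columns: ", path, call. = FALSE)
  data.frame(chrom = as.character(x$chrom), pos = as.integer(x$pos),
             stringsAsFactors = FALSE)
}

#' Read the annotated editing-site database
#'
#' @param path TSV with columns `chrom`, `pos` and optionally `strand`;
#'   `strand` values `.` or `NA` mark strandless records (the source
#'   databases differ in whether they report strand).
#' @return Data.frame with columns `chrom`, `pos`, `strand` (may be `NA`).
#' @export
read_db_sites <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(x)))
    stop("annotated-site table lacks chrom/pos columns: ", path,
         call. = FALSE)
  strand <- if ("strand" %in% names(x)) as.character(x$strand)
            else rep(NA_character_, nrow(x))
  strand[!strand %in% c("+", "-")] <- NA_character_
  data.frame(chrom = as.character(x$chrom), pos = as.integer(x$pos),
             strand = strand, stringsAsFactors = FALSE)
}

#' Expand a BedGraph alignability track to per-position scores
#'
#' Positions with no BedGraph record get score 0 (uniqueness must be
#' positively demonstrated for a site to survive the mappability filter).
#'
#' @param path BedGraph file.
#' @param seqlens Named integer vector of contig lengths.
#' @return A per-contig list of numeric run-length encoded vectors
#'   covering every contig in `seqlens`.
#' @export
read_mappability_track <- function(path, seqlens) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  .check_contigs(as.character(GenomeInfoDb::seqlevels(gr)), names(seqlens))
  gr <- GenomeInfoDb::keepSeqlevels(gr, names(seqlens),
                                    pruning.mode = "coarse")
  GenomeInfoDb::seqlengths(gr) <- seqlens
  if (length(gr) && (min(gr$score) < 0 || max(gr$score) > 1))
    stop("alignability scores outside [0, 1] in ", path, call. = FALSE)
  as.list(GenomicRanges::coverage(gr, weight = "score"))
}
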