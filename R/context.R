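#' Strand-aware overlap of sites with an interval set
#'
#' @param sites Data.frame of sites (`chrom`, `pos`, `strand`).
#' @param intervals A GRanges.
#' @param require_same_strand When TRUE only intervals on the site's
#'   strand count as hits (transcript-sense overlap); when FALSE strand is
#'   ignored.
#' @return Data.frame with columns `site` and `interval` (row/element
#'   indices of each containment hit).
#' @export
overlap_stranded <- function(sites, intervals, require_same_strand = TRUE) {
  if (nrow(sites) == 0L || length(intervals) == 0L)
    return(data.frame(site = integer(), interval = integer()))
  gr <- .sites_gr(sites)
  hits <- GenomicRanges::findOverlaps(gr, intervals, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (require_same_strand) {
    same <- as.character(GenomicRanges::strand(intervals))[s] ==
      sites$strand[q]
    q <- q[same]; s <- s[same]
  }
  data.frame(site = q, interval = s)
}

#' Split sites into annotated and unannotated against the editing database
#'
#' A site matches a database record at the same (chrom, pos); when the
#' record carries a strand it must also match, while strandless records
#' (the source databases differ in strand reporting) match either strand.
#'
#' @param sites Data.frame of sites.
#' @param db_sites Data.frame (`chrom`, `pos`, `strand` possibly `NA`) as
#'   from [read_db_sites()].
#' @return Logical vector, TRUE where the site is annotated.
#' @export
match_annotated_db <- function(sites, db_sites) {
  if (nrow(sites) == 0L) return(logical(0))
  if (nrow(db_sites) == 0L) return(rep(FALSE, nrow(sites)))
  strandless <- is.na(db_sites$strand)
  hit_pos <- .pos_key(sites$chrom, sites$pos) %in%
    .pos_key(db_sites$chrom[strandless], db_sites$pos[strandless])
  hit_str <- .site_key(sites$chrom, sites$pos, sites$strand) %in%
    .site_key(db_sites$chrom[!strandless], db_sites$pos[!strandless],
              db_sites$strand[!strandless])
  hit_pos | hit_str
}

#' Assign each site a single genomic-context label
#'
#' Labels are mutually exclusive under a fixed precedence: CDS, 5' UTR,
#' 3' UTR, lncRNA exon, intron, vlincRNA, antisense exon, antisense
#' intron, intergenic.  Sense categories (1-6) require the site and
#' feature strand to match — an editing site in a transcript must lie on
#' the transcript's strand to be a substrate; antisense categories fire
#' only when the sole overlap is with the opposite strand of an exon or
#' intron.  A same-strand intron wins over a same-strand vlincRNA, so a
#' vlincRNA label means the site is in a vlincRNA and not intronic in any
#' annotated gene.  When a position is exonic in one transcript and
#' intronic in another, the exonic label wins.
#'
#' @param sites Data.frame of sites.
#' @param bundle An [read_annotation_bundle()] object (or any list with
#'   `features` and `vlincs` GRanges).
#' @return Factor of context labels with levels in precedence order.
#' @export
classify_context <- function(sites, bundle) {
  n <- nrow(sites)
  out <- rep(NA_character_, n)
  if (n == 0L)
    return(factor(out, levels = .CONTEXT_LEVELS))
  feats <- bundle$features
  ftype <- if (length(feats)) as.character(feats$type) else character()
  sense_hit <- function(gr) {
    h <- overlap_stranded(sites, gr, require_same_strand = TRUE)
    seq_len(n) %in% h$site
  }
  anti_hit <- function(gr) {
    h <- overlap_stranded(sites, gr, require_same_strand = FALSE)
    opp <- as.character(GenomicRanges::strand(gr))[h$interval] !=
      sites$strand[h$site]
    seq_len(n) %in% h$site[opp]
  }
  sel <- function(ty) feats[ftype == ty]
  classes <- list(
    CDS = sense_hit(sel("CDS")),
    UTR5 = sense_hit(sel("UTR5")),
    UTR3 = sense_hit(sel("UTR3")),
    lncRNA_exon = sense_hit(sel("lncRNA_exon")),
    intron = sense_hit(sel("intron")),
    vlincRNA = sense_hit(bundle$vlincs),
    antisense_exon = anti_hit(sel("exon")),
    antisense_intron = anti_hit(sel("intron")))
  for (lab in names(classes)) {
    take <- is.na(out) & classes[[lab]]
    out[take] <- lab
  }
  out[is.na(out)] <- "intergenic"
  factor(out, levels = .CONTEXT_LEVELS)
}
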