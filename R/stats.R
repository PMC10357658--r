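#' Population-weighted Sanger validation ratio
#'
#' Sanger validation tests only a sample of each stratum of sites, so the
#' per-stratum validation ratios (positive / tested) are averaged with the
#' stratum population sizes as weights: `sum(N_g * p_g / t_g) / sum(N_g)`.
#' Equivalently, every member of a stratum is assigned its stratum's
#' ratio and the ratios are averaged over the whole population.
#'
#' @param strata Data.frame with columns `population` and either
#'   `positive` and `tested` counts or a precomputed `ratio` (fraction in
#'   \[0, 1\]); an optional `label` column names strata in error messages.
#' @return The weighted ratio as a fraction in \[0, 1\].
#' @examples
#' # annotated and unannotated sites detected in >= 2 samples
#' strata <- data.frame(population = c(3196, 8724),
#'                      positive = c(69, 52), tested = c(110, 215))
#' 100 * weighted_validation_ratio(strata)  # 34.5%
#' @export
weighted_validation_ratio <- function(strata) {
  stopifnot(is.data.frame(strata), nrow(strata) >= 1L,
            "population" %in% names(strata))
  if (any(strata$population <= 0))
    stop("stratum population must be positive", call. = FALSE)
  if ("ratio" %in% names(strata)) {
    r <- strata$ratio
    stopifnot(all(r >= 0 & r <= 1))
  } else {
    if (!all(c("positive", "tested") %in% names(strata)))
      stop("strata need either a ratio column or positive/tested counts",
           call. = FALSE)
    bad <- strata$tested <= 0
    if (any(bad)) {
      lab <- if ("label" %in% names(strata)) strata$label[bad]
             else which(bad)
      stop("stratum with no tested sites: ",
           paste(lab, collapse = ", "), call. = FALSE)
    }
    stopifnot(all(strata$positive >= 0),
              all(strata$positive <= strata$tested))
    r <- strata$positive / strata$tested
  }
  sum(strata$population * r) / sum(strata$population)
}

#' Minimal false-positive fraction from tested and untested strata
#'
#' Combines the observed Sanger failure rate of a tested stratum with an
#' assumed failure rate for an untested stratum into a lower bound on the
#' overall false-positive fraction.  Expected failure counts are rounded
#' to the nearest integer per stratum before summation, matching how such
#' tallies are reported.
#'
#' @param tested_population Number of sites in the Sanger-characterised
#'   stratum.
#' @param tested_fail_rate Observed failure rate of that stratum (e.g.
#'   one minus its weighted validation ratio).
#' @param untested_population Number of sites in the uncharacterised
#'   stratum.
#' @param untested_fail_rate Failure rate assumed for it.
#' @return Fraction in \[0, 1\].
#' @examples
#' estimate_min_false_fraction(3160, 0.255, 2630, 0.765)  # 0.487
#' @export
estimate_min_false_fraction <- function(tested_population,
                                        tested_fail_rate,
                                        untested_population,
                                        untested_fail_rate) {
  stopifnot(tested_population > 0, untested_population >= 0,
            tested_fail_rate >= 0, tested_fail_rate <= 1,
            untested_fail_rate >= 0, untested_fail_rate <= 1)
  fails <- round(tested_population * tested_fail_rate) +
    round(untested_population * untested_fail_rate)
  fails / (tested_population + untested_population)
}

#' Enrichment odds ratios of sites across genomic elements
#'
#' For each element class, forms the 2x2 table of site counts inside vs
#' outside the element against background position counts inside vs
#' outside, and reports the cross-product odds ratio `(a*d)/(b*c)`.  A
#' zero denominator yields `NA` with `undefined = TRUE` rather than an
#' infinite value.
#'
#' @param site_counts Named integer vector of site counts per element.
#' @param background_counts Named integer vector of background position
#'   counts per element (same names).
#' @return Data.frame with columns `element`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `undefined`.
#' @examples
#' odds_ratio_enrichment(c(CDS = 10, intron = 90),
#'                       c(CDS = 1000, intron = 99000))
#' @export
odds_ratio_enrichment <- function(site_counts, background_counts) {
  stopifnot(length(site_counts) == length(background_counts),
            !is.null(names(site_counts)),
            setequal(names(site_counts), names(background_counts)))
  background_counts <- background_counts[names(site_counts)]
  tot_a <- sum(site_counts)
  tot_c <- sum(background_counts)
  a <- as.numeric(site_counts)
  b <- tot_a - a
  cc <- as.numeric(background_counts)
  d <- tot_c - cc
  undef <- (b * cc) == 0
  or <- ifelse(undef, NA_real_, (a * d) / (b * cc))
  data.frame(element = names(site_counts), a = a, b = b, c = cc, d = d,
             odds_ratio = or, undefined = undef,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count editable background positions per genomic element
#'
#' The enrichment background is the number of strand-resolved adenosines
#' (A on `+`, T on `-`) in each context class over the non-repeat,
#' uniquely mappable (100mer score 1) portion of the genome — i.e. the
#' positions where the pipeline could in principle have reported a site.
#' Classes are made mutually exclusive with the same precedence as
#' [classify_context()].
#'
#' @param bundle An [read_annotation_bundle()] object.
#' @return Named integer vector over the context labels.
#' @export
count_editable_background <- function(bundle) {
  seqlens <- bundle$seqlens
  genome_gr <- GenomicRanges::GRanges(
    seqnames = names(seqlens),
    ranges = IRanges::IRanges(1L, as.integer(seqlens)))
  both_strands <- function(gr) {
    g1 <- gr; GenomicRanges::strand(g1) <- "+"
    g2 <- gr; GenomicRanges::strand(g2) <- "-"
    c(g1, g2)
  }
  flip <- function(gr) {
    s <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(s == "+", "-", "+")
    gr
  }
  feats <- bundle$features
  ftype <- if (length(feats)) as.character(feats$type) else character()
  sel <- function(ty) feats[ftype == ty]
  class_regions <- list(
    CDS = sel("CDS"), UTR5 = sel("UTR5"), UTR3 = sel("UTR3"),
    lncRNA_exon = sel("lncRNA_exon"), intron = sel("intron"),
    vlincRNA = bundle$vlincs,
    antisense_exon = flip(sel("exon")),
    antisense_intron = flip(sel("intron")),
    intergenic = both_strands(genome_gr))

  # eligible positions: outside repeats, 100mer-unique
  mask <- GenomicRanges::reduce(GenomicRanges::granges(bundle$repeats),
                                ignore.strand = TRUE)
  uniq <- .rle_regions(bundle$map100, function(v) v >= 1 - 1e-9)
  remaining <- both_strands(
    GenomicRanges::intersect(
      GenomicRanges::setdiff(genome_gr, mask, ignore.strand = TRUE),
      uniq, ignore.strand = TRUE))

  counts <- stats::setNames(integer(length(class_regions)),
                            names(class_regions))
  for (lab in names(class_regions)) {
    reg <- GenomicRanges::reduce(class_regions[[lab]])
    take <- GenomicRanges::intersect(remaining, reg,
                                     ignore.strand = FALSE)
    counts[lab] <- .count_stranded_adenosines(bundle$genome, take)
    remaining <- GenomicRanges::setdiff(remaining, take,
                                        ignore.strand = FALSE)
  }
  counts
}

# regions of an Rle track list where pred(value) holds, as a GRanges
.rle_regions <- function(track, pred) {
  parts <- lapply(names(track), function(chrom) {
    r <- track[[chrom]]
    ok <- pred(S4Vectors::runValue(r))
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    if (!any(ok)) return(NULL)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts[ok], ends[ok]))
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(do.call(c, parts))
}

# number of A (on '+') plus T (on '-') positions in stranded regions
.count_stranded_adenosines <- function(genome, gr) {
  if (!length(gr)) return(0L)
  total <- 0L
  for (chrom in unique(as.character(GenomicRanges::seqnames(gr)))) {
    sub <- gr[GenomicRanges::seqnames(gr) == chrom]
    seqs <- Biostrings::extractAt(
      genome[[chrom]],
      IRanges::IRanges(GenomicRanges::start(sub), GenomicRanges::end(sub)))
    af <- Biostrings::letterFrequency(seqs, c("A", "T"))
    plus <- as.character(GenomicRanges::strand(sub)) == "+"
    total <- total + sum(af[plus, "A"]) + sum(af[!plus, "T"])
  }
  as.integer(total)
}
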