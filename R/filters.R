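#' Remove candidate calls at known variant positions
#'
#' DNA sequence variants produce apparent A-to-G changes in every read and
#' are the classic editing false positive, so any call whose (chrom, pos)
#' coincides with a known variant is removed.  Matching is strandless: a
#' DNA variant affects both strands.
#'
#' @param calls Data.frame of calls (columns `chrom`, `pos`, `strand`, ...).
#' @param variants Data.frame of variant positions (`chrom`, `pos`,
#'   1-based); may be empty.
#' @return List with elements `pass` and `removed`, partitioning `calls`.
#' @export
filter_variants <- function(calls, variants) {
  if (nrow(calls) == 0L || nrow(variants) == 0L)
    return(list(pass = calls, removed = calls[0, , drop = FALSE]))
  hit <- .pos_key(calls$chrom, calls$pos) %in%
    .pos_key(variants$chrom, variants$pos)
  list(pass = calls[!hit, , drop = FALSE],
       removed = calls[hit, , drop = FALSE])
}

#' Remove candidate calls inside annotated repeats
#'
#' Repeat-derived mis-mapping is a major false-positive source; editing in
#' repeats (mostly Alu) is also biologically distinct, so the pipeline is
#' restricted to the non-repeat genome.  Repeat masking is strandless.
#'
#' @param calls Data.frame of calls.
#' @param repeats GRanges of repeat intervals; the `name` metadata column,
#'   when present, carries the repeat family (entries containing `"Alu"`
#'   count toward the Alu fraction).
#' @return List with `pass`, `removed`, and `alu_fraction_of_removed`
#'   (0 when nothing was removed).
#' @export
filter_repeats <- function(calls, repeats) {
  if (nrow(calls) == 0L || length(repeats) == 0L)
    return(list(pass = calls, removed = calls[0, , drop = FALSE],
                alu_fraction_of_removed = 0))
  gr <- .sites_gr(calls, use_strand = FALSE)
  hits <- GenomicRanges::findOverlaps(gr, repeats, ignore.strand = TRUE)
  removed_idx <- unique(S4Vectors::queryHits(hits))
  hit <- seq_len(nrow(calls)) %in% removed_idx
  alu_frac <- 0
  if (length(removed_idx)) {
    fam <- if (!is.null(repeats$name)) as.character(repeats$name)
           else rep("", length(repeats))
    in_alu <- tapply(grepl("Alu", fam[S4Vectors::subjectHits(hits)]),
                     S4Vectors::queryHits(hits), any)
    alu_frac <- mean(in_alu)
  }
  list(pass = calls[!hit, , drop = FALSE],
       removed = calls[hit, , drop = FALSE],
       alu_fraction_of_removed = alu_frac)
}

#' Remove candidate calls in poorly mappable regions
#'
#' A call passes iff the 100mer alignability score at its position equals
#' the required score (default 1, i.e. the 100mer starting there maps
#' uniquely) and the mean 24mer alignability over the window of
#' `2 * map_window + 1` positions centred on the site is strictly greater
#' than `map24_mean_min`.  The window mean is always taken over the full
#' window size: positions beyond the contig ends, and positions with no
#' track record, contribute score 0, which biases the rule toward
#' rejection near assembly edges and unannotated regions.
#'
#' @param calls Data.frame of calls.
#' @param map100,map24 Per-contig numeric Rle lists as produced by
#'   [read_mappability_track()].
#' @param config A [pipeline_config()].
#' @return List with `pass` and `removed`.
#' @export
filter_mappability <- function(calls, map100, map24,
                               config = pipeline_config()) {
  if (nrow(calls) == 0L)
    return(list(pass = calls, removed = calls))
  w <- config$map_window
  nslots <- 2L * w + 1L
  keep <- logical(nrow(calls))
  for (chrom in unique(calls$chrom)) {
    idx <- which(calls$chrom == chrom)
    pos <- calls$pos[idx]
    if (!chrom %in% names(map100) || !chrom %in% names(map24)) {
      warning("contig ", chrom, " absent from mappability tracks; ",
              length(idx), " call(s) removed", call. = FALSE)
      next
    }
    t100 <- map100[[chrom]]
    t24 <- map24[[chrom]]
    len <- length(t24)
    in100 <- pos <= length(t100)
    s100 <- numeric(length(pos))
    s100[in100] <- as.numeric(t100[pos[in100]])
    pass100 <- s100 >= config$map100_required - 1e-9
    # windowed sums via cumulative sums of the expanded track
    cs <- c(0, cumsum(as.numeric(t24)))
    lo <- pmax(pos - w, 1L)
    hi <- pmin(pos + w, len)
    wsum <- ifelse(hi >= lo, cs[hi + 1L] - cs[lo], 0)
    pass24 <- (wsum / nslots) > config$map24_mean_min
    keep[idx] <- pass100 & pass24
  }
  list(pass = calls[keep, , drop = FALSE],
       removed = calls[!keep, , drop = FALSE])
}

#' Apply the pre-consensus candidate filters in the fixed order
#'
#' Variants, then repeats, then mappability.  Every input call lands in
#' exactly one bin, so the report tallies are conserved.
#'
#' @param calls Data.frame of calls.
#' @param bundle An [read_annotation_bundle()] object.
#' @param config A [pipeline_config()].
#' @return List with `pass` (surviving calls), `removed` (list of the
#'   three removed bins) and `report`, a one-row data.frame of class
#'   `"filter_report"` with counts `n_input`, `n_removed_variant`,
#'   `n_removed_repeat`, `repeat_alu_fraction`, `n_removed_mappability`,
#'   `n_pass`.
#' @export
filter_candidates <- function(calls, bundle, config = pipeline_config()) {
  fv <- filter_variants(calls, bundle$variants)
  fr <- filter_repeats(fv$pass, bundle$repeats)
  fm <- filter_mappability(fr$pass, bundle$map100, bundle$map24, config)
  report <- data.frame(
    n_input = nrow(calls),
    n_removed_variant = nrow(fv$removed),
    n_removed_repeat = nrow(fr$removed),
    repeat_alu_fraction = fr$alu_fraction_of_removed,
    n_removed_mappability = nrow(fm$removed),
    n_pass = nrow(fm$pass))
  class(report) <- c("filter_report", "data.frame")
  stopifnot(report$n_input == report$n_removed_variant +
              report$n_removed_repeat + report$n_removed_mappability +
              report$n_pass)
  list(pass = fm$pass,
       removed = list(variant = fv$removed, repeat_ = fr$removed,
                      mappability = fm$removed),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("candidate filter report\n")
  cat(sprintf("  input calls        : %d\n", x$n_input))
  cat(sprintf("  removed: variants  : %d\n", x$n_removed_variant))
  cat(sprintf("  removed: repeats   : %d (Alu fraction %.3f)\n",
              x$n_removed_repeat, x$repeat_alu_fraction))
  cat(sprintf("  removed: mappability: %d\n", x$n_removed_mappability))
  cat(sprintf("  passing            : %d\n", x$n_pass))
  invisible(x)
}
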