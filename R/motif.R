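#' Base-fraction profile around editing sites
#'
#' Extracts the transcript-sense sequence in a window of `halfwidth` bases
#' on each side of every site (reverse-complemented for minus-strand
#' sites), and tabulates the fraction of each base (A, C, G, U — RNA
#' alphabet, T reported as U) at each window position.  Position 0 is the
#' edited adenosine, so its A fraction is 1 by construction; sites whose
#' strand base is not A indicate upstream corruption and are excluded
#' with a warning, as are sites too close to a contig end for a full
#' window.
#'
#' @param sites Data.frame of sites (`chrom`, `pos`, `strand`).
#' @param genome A `DNAStringSet` (e.g. `bundle$genome`).
#' @param halfwidth Window half-width in bp (default 5).
#' @return Object of class `"motif_profile"`: list with `fractions` (4 x
#'   (2*halfwidth+1) matrix, rows A/C/G/U, columns labelled -halfwidth ..
#'   halfwidth), `n` (sequences used), `halfwidth`.
#' @export
motif_profile <- function(sites, genome, halfwidth = 5L) {
  halfwidth <- as.integer(halfwidth)
  stopifnot(halfwidth >= 1L)
  width <- 2L * halfwidth + 1L
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  known <- sites$chrom %in% names(genome)
  fits <- rep(FALSE, nrow(sites))
  fits[known] <- sites$pos[known] - halfwidth >= 1L &
    sites$pos[known] + halfwidth <= seqlens[sites$chrom[known]]
  if (any(!fits))
    warning(sum(!fits), " site(s) skipped: window extends beyond the ",
            "contig", call. = FALSE)
  sites <- sites[fits, , drop = FALSE]
  seq_parts <- lapply(unique(sites$chrom), function(chrom) {
    idx <- sites$chrom == chrom
    Biostrings::extractAt(
      genome[[chrom]],
      IRanges::IRanges(sites$pos[idx] - halfwidth,
                       sites$pos[idx] + halfwidth))
  })
  seqs <- if (length(seq_parts)) do.call(c, seq_parts)
          else Biostrings::DNAStringSet()
  # extraction above groups sites by contig; realign to input order
  ord <- order(match(sites$chrom, unique(sites$chrom)))
  strand <- sites$strand[ord]
  minus <- strand == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  centre <- as.character(Biostrings::subseq(seqs, halfwidth + 1L,
                                            halfwidth + 1L))
  bad <- centre != "A"
  if (any(bad)) {
    warning(sum(bad), " site(s) excluded: strand base at the site is ",
            "not A (possible coordinate or strand corruption)",
            call. = FALSE)
    seqs <- seqs[!bad]
  }
  n <- length(seqs)
  if (n == 0L) {
    fr <- matrix(NA_real_, 4L, width,
                 dimnames = list(c("A", "C", "G", "U"),
                                 as.character(seq(-halfwidth, halfwidth))))
    return(structure(list(fractions = fr, n = 0L, halfwidth = halfwidth),
                     class = "motif_profile"))
  }
  cm <- Biostrings::consensusMatrix(seqs, baseOnly = TRUE)
  fr <- cm[c("A", "C", "G", "T"), , drop = FALSE] / n
  rownames(fr) <- c("A", "C", "G", "U")
  colnames(fr) <- as.character(seq(-halfwidth, halfwidth))
  structure(list(fractions = fr, n = n, halfwidth = halfwidth),
            class = "motif_profile")
}

#' Difference between two base-fraction profiles
#'
#' Subtracts the second profile's per-position base fractions from the
#' first's; positive values mean the base is enriched in the first set
#' (e.g. true sites vs failed sites).  At every position the four base
#' differences sum to zero.
#'
#' @param profile_pos,profile_neg `"motif_profile"` objects with the same
#'   half-width.
#' @return Matrix of differences (rows A/C/G/U).
#' @export
motif_difference <- function(profile_pos, profile_neg) {
  stopifnot(inherits(profile_pos, "motif_profile"),
            inherits(profile_neg, "motif_profile"))
  if (profile_pos$halfwidth != profile_neg$halfwidth)
    stop("motif profiles have different half-widths", call. = FALSE)
  profile_pos$fractions - profile_neg$fractions
}

#' @export
print.motif_profile <- function(x, digits = 3, ...) {
  cat(sprintf("motif profile over %d sequence(s), positions %+d..%+d\n",
              x$n, -x$halfwidth, x$halfwidth))
  print(round(x$fractions, digits))
  invisible(x)
}

#' @export
plot.motif_profile <- function(x, ...) {
  pos <- as.integer(colnames(x$fractions))
  graphics::matplot(pos, t(x$fractions), type = "b", pch = rownames(
    x$fractions), lty = 1, xlab = "position relative to edited A",
    ylab = "base fraction", ...)
  invisible(x)
}
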