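#' Aggregate per-method editing levels within one sample
#'
#' When several callers detect the same site in the same sample, the
#' site's editing level in that sample is the arithmetic mean of the
#' levels the detecting callers report.
#'
#' @param levels Numeric vector of per-method editing levels (1 to one per
#'   method), each in \[0, 1\].
#' @return The arithmetic mean.
#' @examples
#' aggregate_sample_level(c(0.2, 0.4))
#' @export
aggregate_sample_level <- function(levels) {
  if (length(levels) == 0L)
    stop("aggregate_sample_level() requires at least one level",
         call. = FALSE)
  stopifnot(all(levels >= 0 & levels <= 1))
  mean(levels)
}

#' Merge filtered calls into per-site consensus records
#'
#' One record per distinct (chrom, pos, strand).  Within each sample the
#' per-method levels are averaged ([aggregate_sample_level()]); across
#' samples the site keeps the maximum aggregated level and the number of
#' samples with any call.  The method set is the union across all samples:
#' a site found by RED-ML in one sample and by SPRINT in another counts as
#' found by both methods, even if only one sample's level passes the
#' downstream threshold.  HPC-REDItools evidence is recorded in
#' `methods_all` but excluded from `methods`, the set used by all
#' decision rules.
#'
#' @param calls Data.frame of filtered calls.
#' @return Data.frame of class `"consensus_sites"` with columns `chrom`,
#'   `pos`, `strand`, `methods` (comma-joined sorted decision-method set),
#'   `methods_all`, `n_samples`, `max_level`; per-sample aggregated levels
#'   in `attr(x, "per_sample")`.
#' @export
build_consensus <- function(calls) {
  if (nrow(calls) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), methods = character(),
                      methods_all = character(), n_samples = integer(),
                      max_level = numeric(), stringsAsFactors = FALSE)
    attr(out, "per_sample") <- data.frame(
      chrom = character(), pos = integer(), strand = character(),
      sample_id = character(), level = numeric(), methods = character(),
      stringsAsFactors = FALSE)
    class(out) <- c("consensus_sites", "data.frame")
    return(out)
  }
  .assert_strand(calls$strand)
  sk <- .site_key(calls$chrom, calls$pos, calls$strand)
  ssk <- paste(sk, calls$sample_id, sep = "\r")
  f <- factor(ssk, levels = unique(ssk))
  level <- as.numeric(tapply(calls$editing_level, f, aggregate_sample_level))
  meth_in_sample <- tapply(calls$method_id, f, function(m)
    paste(sort(unique(m)), collapse = ","))
  first <- !duplicated(f)
  per_sample <- data.frame(
    chrom = calls$chrom[first], pos = calls$pos[first],
    strand = calls$strand[first], sample_id = calls$sample_id[first],
    level = level, methods = as.character(meth_in_sample),
    stringsAsFactors = FALSE)

  sk2 <- .site_key(per_sample$chrom, per_sample$pos, per_sample$strand)
  f2 <- factor(sk2, levels = unique(sk2))
  first2 <- !duplicated(f2)
  methods_of <- function(keep) {
    ms <- tapply(calls$method_id, factor(sk, levels = levels(f2)),
                 function(m) paste(sort(intersect(unique(m), keep)),
                                   collapse = ","))
    as.character(ms)
  }
  out <- data.frame(
    chrom = per_sample$chrom[first2],
    pos = per_sample$pos[first2],
    strand = per_sample$strand[first2],
    methods = methods_of(.DECISION_METHODS),
    methods_all = methods_of(.ALL_METHODS),
    n_samples = as.integer(tapply(per_sample$sample_id, f2,
                                  function(s) length(unique(s)))),
    max_level = as.numeric(tapply(per_sample$level, f2, max)),
    stringsAsFactors = FALSE)
  o <- order(out$chrom, out$pos, out$strand)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  class(out) <- c("consensus_sites", "data.frame")
  out
}

#' Apply the editing-level and reproducibility thresholds
#'
#' A site is retained iff its maximum aggregated editing level across
#' samples strictly exceeds `config$level_threshold` (a site at exactly
#' the threshold is excluded) and it was called in at least
#' `config$min_samples` samples by any method.
#'
#' @param sites A [build_consensus()] data.frame.
#' @param config A [pipeline_config()].
#' @return List with `retained` and `singleton_or_low`.
#' @export
apply_reproducibility_thresholds <- function(sites,
                                             config = pipeline_config()) {
  keep <- sites$max_level > config$level_threshold &
    sites$n_samples >= config$min_samples
  list(retained = sites[keep, , drop = FALSE],
       singleton_or_low = sites[!keep, , drop = FALSE])
}

#' Label sites by method specificity
#'
#' A site is method-specific only when every sample's detection came from
#' that one caller; any cross-sample or within-sample combination makes it
#' multi-method.  HPC-REDItools is auxiliary and never defines
#' specificity; sites with only auxiliary evidence get `NA`.
#'
#' @param sites A [build_consensus()] data.frame.
#' @return Character vector: `"<method>-specific"` or `"multi-method"`.
#' @export
classify_method_specificity <- function(sites) {
  n <- lengths(strsplit(sites$methods, ",", fixed = TRUE))
  out <- ifelse(n == 1L, paste0(sites$methods, "-specific"), "multi-method")
  out[!nzchar(sites$methods)] <- NA_character_
  out
}
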