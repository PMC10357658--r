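#' Read a normalized candidate-call table for one sample and one method
#'
#' Editing callers emit incompatible native formats; the pipeline consumes
#' a single normalized tab-separated dialect instead, one row per candidate
#' A-to-G change: columns `chrom`, `pos` (1-based coordinate of the edited
#' adenosine), `strand` (`+`/`-`; on `-` the forward-strand change is
#' T-to-C), `editing_level` (edited reads / total reads, in \[0, 1\]) and
#' `coverage` (total reads).  Rows violating the field invariants are
#' dropped with a message; a missing column is a format error.
#'
#' @param path Path to the TSV file (header required).
#' @param sample_id Sample identifier attached to every row.
#' @param method_id Caller identifier; one of `"REDItools"`, `"RED-ML"`,
#'   `"SPRINT"`, `"HPC-REDItools"`.
#' @return A data.frame of validated calls with columns `chrom`, `pos`,
#'   `strand`, `editing_level`, `coverage`, `sample_id`, `method_id`.  The
#'   number of rejected rows is available as `attr(x, "n_rejected")`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tstrand\tediting_level\tcoverage",
#'              "chr1\t100\t+\t0.30\t25"), f)
#' read_method_calls(f, "s1", "RED-ML")
#' @export
read_method_calls <- function(path, sample_id, method_id) {
  if (!file.exists(path)) stop("call table not found: ", path, call. = FALSE)
  if (!method_id %in% .ALL_METHODS)
    stop("unknown method_id '", method_id, "'; expected one of ",
         paste(.ALL_METHODS, collapse = ", "), call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  required <- c("chrom", "pos", "strand", "editing_level", "coverage")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("call table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- x[required]
  if (nrow(x) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), editing_level = numeric(),
                      coverage = integer(), sample_id = character(),
                      method_id = character(), stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$editing_level <- suppressWarnings(as.numeric(x$editing_level))
  x$coverage <- suppressWarnings(as.integer(x$coverage))
  ok <- !is.na(x$pos) & x$pos >= 1L &
    x$strand %in% c("+", "-") &
    !is.na(x$editing_level) & x$editing_level >= 0 & x$editing_level <= 1 &
    !is.na(x$coverage) & x$coverage >= 0L
  n_rej <- sum(!ok)
  if (n_rej > 0L)
    message(n_rej, " of ", nrow(x), " rows in ", basename(path),
            " rejected (invariant violations)")
  x <- x[ok, , drop = FALSE]
  # duplicate (site, sample, method) observations are not meaningful
  dup <- duplicated(.site_key(x$chrom, x$pos, x$strand))
  if (any(dup)) {
    message(sum(dup), " duplicated site row(s) in ", basename(path),
            " dropped")
    x <- x[!dup, , drop = FALSE]
  }
  x$sample_id <- sample_id
  x$method_id <- method_id
  rownames(x) <- NULL
  attr(x, "n_rejected") <- n_rej
  x
}

#' Read a directory of normalized call tables
#'
#' Files must be named `<sample_id>__<method_id>.tsv`; every file is read
#' with [read_method_calls()] and the results are concatenated.
#'
#' @param dir Directory containing the call tables.
#' @return A single data.frame of calls (possibly zero rows).
#' @export
read_calls_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  parts <- lapply(files, function(f) {
    stem <- sub("\\.tsv$", "", basename(f))
    bits <- strsplit(stem, "__", fixed = TRUE)[[1]]
    if (length(bits) != 2L)
      stop("call file name must be <sample>__<method>.tsv: ", basename(f),
           call. = FALSE)
    read_method_calls(f, bits[1], bits[2])
  })
  if (!length(parts)) {
    out <- read_method_calls(
      {f <- tempfile(); writeLines(
        "chrom\tpos\tstrand\tediting_level\tcoverage", f); f},
      "none", "REDItools")
    return(out[0, , drop = FALSE])
  }
  do.call(rbind, parts)
}

#' Read Sanger validation outcomes
#'
#' Each record is the outcome of validating one site in one RNA sample:
#' the RNA trace either shows the A/G mixture (`rna_outcome = "edited"`) or
#' not, and the genomic DNA trace is either homozygous reference, a
#' sequence variant (the A/G mixture is present in DNA, i.e. a SNP
#' masquerading as editing), or untested.  `status` must be consistent:
#' `validated` iff RNA edited and gDNA homozygous reference;
#' `sequence_variant` iff gDNA shows the variant.  The `adjacent` column
#' lists additional editing sites discovered in the same trace as
#' comma-separated `chrom:pos:strand` triplets (may be empty).
#'
#' @param path TSV with columns `chrom`, `pos`, `strand`, `tested_sample`,
#'   `rna_outcome`, `gdna_outcome`, `status`, `adjacent`.
#' @return Data.frame of validation records; `adjacent` is a list column
#'   of site data.frames.
#' @export
read_validation_records <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "strand", "tested_sample",
                "rna_outcome", "gdna_outcome", "status", "adjacent")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("validation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  stopifnot(all(x$rna_outcome %in% c("edited", "not_detected")),
            all(x$gdna_outcome %in%
                  c("homozygous_reference", "variant", "not_tested")),
            all(x$status %in% c("validated", "failed", "sequence_variant")))
  ok_val <- (x$status == "validated") ==
    (x$rna_outcome == "edited" & x$gdna_outcome == "homozygous_reference")
  ok_var <- (x$status == "sequence_variant") == (x$gdna_outcome == "variant")
  if (!all(ok_val & ok_var))
    stop("inconsistent validation record(s) at row(s): ",
         paste(utils::head(which(!(ok_val & ok_var)), 5), collapse = ", "),
         call. = FALSE)
  x$adjacent <- lapply(x$adjacent, parse_adjacent_sites)
  x
}

# "chr1:100:+,chr1:103:-" -> site data.frame
parse_adjacent_sites <- function(s) {
  if (is.na(s) || !nzchar(s)) return(.empty_sites())
  bits <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(bits, length, 1L) != 3L
  if (any(bad)) stop("malformed adjacent-site entry: ", s, call. = FALSE)
  data.frame(chrom = vapply(bits, `[`, "", 1L),
             pos = as.integer(vapply(bits, `[`, "", 2L)),
             strand = vapply(bits, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
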