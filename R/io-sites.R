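#' Write a consensus/compendium site table
#'
#' Writes a TSV with columns `chrom`, `pos` (1-based), `strand`,
#' `methods`, `n_samples`, `max_level`, `annotated`, `context`, `final`,
#' in deterministic (chrom, pos, strand) order.  `max_level` is printed
#' with 17 significant digits so a read-back reproduces the double
#' exactly.  Missing columns are filled with `NA` so partial tables (e.g.
#' pre-annotation consensus) can be serialized too.
#'
#' @param sites Data.frame of sites.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_site_table <- function(sites, path) {
  cols <- c("chrom", "pos", "strand", "methods", "n_samples", "max_level",
            "annotated", "context", "final")
  out <- data.frame(row.names = seq_len(nrow(sites)))
  for (col in cols)
    out[[col]] <- if (!is.null(sites[[col]])) sites[[col]]
                  else rep(NA, nrow(sites))
  o <- order(out$chrom, out$pos, out$strand)
  out <- out[o, , drop = FALSE]
  out$max_level <- ifelse(is.na(out$max_level), NA,
                          sprintf("%.17g", as.numeric(out$max_level)))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write site table to ", path, call. = FALSE)
  invisible(path)
}

#' Read back a site table written by [write_site_table()]
#'
#' @param path Path to the TSV.
#' @return Data.frame with typed columns (`context` as a factor over the
#'   standard labels).
#' @export
read_site_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        strand = "character",
                                        methods = "character",
                                        context = "character"))
  x$pos <- as.integer(x$pos)
  x$n_samples <- as.integer(x$n_samples)
  x$max_level <- as.numeric(x$max_level)
  x$annotated <- as.logical(x$annotated)
  x$final <- as.logical(x$final)
  x$context <- factor(x$context, levels = .CONTEXT_LEVELS)
  x$methods[is.na(x$methods)] <- ""
  x
}

#' Export final sites as BED6
#'
#' 1-based site positions become 0-based half-open single-base intervals;
#' the BED score column is `round(1000 * max_level)`.
#'
#' @param sites Data.frame with `chrom`, `pos`, `strand`, `max_level`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_sites_bed <- function(sites, path) {
  lvl <- as.numeric(sites$max_level)
  lvl[is.na(lvl)] <- 0
  o <- order(sites$chrom, sites$pos, sites$strand)
  bed <- data.frame(chrom = sites$chrom[o],
                    start = sites$pos[o] - 1L,
                    end = sites$pos[o],
                    name = sprintf("%s_%d_%s", sites$chrom[o],
                                   sites$pos[o], sites$strand[o]),
                    score = as.integer(round(1000 * lvl[o])),
                    strand = sites$strand[o])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
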