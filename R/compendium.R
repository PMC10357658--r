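#' Final admission rule for annotated sites
#'
#' Among threshold-passing sites that match the editing databases, the
#' final annotated editome is the union of sites detected by RED-ML and
#' SPRINT; sites detected only by REDItools are excluded (they validated
#' at 0% by Sanger).
#'
#' @param sites Consensus data.frame of annotated sites (column `methods`
#'   as comma-joined decision-method set).
#' @return List with `kept` and `excluded`; `excluded` gains a `reason`
#'   column (`"reditools_only"`).
#' @export
finalize_annotated <- function(sites) {
  ms <- strsplit(sites$methods, ",", fixed = TRUE)
  keep <- vapply(ms, function(m) any(c("RED-ML", "SPRINT") %in% m), TRUE)
  excluded <- sites[!keep, , drop = FALSE]
  excluded$reason <- rep("reditools_only", nrow(excluded))
  list(kept = sites[keep, , drop = FALSE], excluded = excluded)
}

#' Final admission rule for unannotated sites
#'
#' Unannotated sites need stronger evidence, dependent on genomic
#' context: a site must be detected by RED-ML, and unless it lies in an
#' intron or a vlincRNA (where RED-ML alone proved reliable) it must also
#' be detected by SPRINT.
#'
#' @param sites Consensus data.frame of unannotated sites with a
#'   `context` column ([classify_context()]).
#' @return List with `kept` and `excluded`; `excluded` gains a `reason`
#'   column (`"no_redml"` or `"no_sprint_outside_intron_vlinc"`).
#' @export
finalize_unannotated <- function(sites) {
  ms <- strsplit(sites$methods, ",", fixed = TRUE)
  has_redml <- vapply(ms, function(m) "RED-ML" %in% m, TRUE)
  has_sprint <- vapply(ms, function(m) "SPRINT" %in% m, TRUE)
  relaxed <- as.character(sites$context) %in% c("intron", "vlincRNA")
  keep <- has_redml & (relaxed | has_sprint)
  excluded <- sites[!keep, , drop = FALSE]
  excluded$reason <- if (nrow(excluded))
    ifelse(!has_redml[!keep], "no_redml", "no_sprint_outside_intron_vlinc")
    else character(0)
  list(kept = sites[keep, , drop = FALSE], excluded = excluded)
}

#' Add unannotated sites discovered during Sanger validation
#'
#' Sanger traces read 150-600 bp around a tested site, and frequently
#' reveal additional A/G mixed positions nearby.  Those adjacent sites
#' join the final unannotated editome unless they duplicate a pipeline
#' site, match the annotated database, or coincide with a known variant
#' position (rejected with a warning).
#'
#' @param kept_unannotated Data.frame of pipeline-admitted unannotated
#'   sites.
#' @param validation Data.frame from [read_validation_records()] (or NULL).
#' @param db_sites Annotated-database data.frame (or NULL).
#' @param variants Known-variant data.frame (or NULL).
#' @return List with `final` (union data.frame, added rows flagged by the
#'   logical `sanger_only` column) and `sanger_added` (just the added
#'   sites).
#' @export
merge_sanger_discovered <- function(kept_unannotated, validation = NULL,
                                    db_sites = NULL, variants = NULL) {
  kept <- kept_unannotated
  if (is.null(kept$sanger_only))
    kept$sanger_only <- rep(FALSE, nrow(kept))
  adj <- if (is.null(validation) || nrow(validation) == 0L) .empty_sites()
         else do.call(rbind, validation$adjacent)
  if (is.null(adj) || nrow(adj) == 0L)
    return(list(final = kept, sanger_added = .empty_sites()))
  adj <- adj[!duplicated(.site_key(adj$chrom, adj$pos, adj$strand)), ,
             drop = FALSE]
  if (!is.null(variants) && nrow(variants)) {
    on_var <- .pos_key(adj$chrom, adj$pos) %in%
      .pos_key(variants$chrom, variants$pos)
    if (any(on_var))
      warning(sum(on_var), " Sanger-adjacent site(s) coincide with known ",
              "variant positions and were rejected", call. = FALSE)
    adj <- adj[!on_var, , drop = FALSE]
  }
  if (!is.null(db_sites) && nrow(db_sites))
    adj <- adj[!match_annotated_db(adj, db_sites), , drop = FALSE]
  if (nrow(kept))
    adj <- adj[!.site_key(adj$chrom, adj$pos, adj$strand) %in%
                 .site_key(kept$chrom, kept$pos, kept$strand), ,
               drop = FALSE]
  if (nrow(adj) == 0L)
    return(list(final = kept, sanger_added = .empty_sites()))
  added <- data.frame(chrom = adj$chrom, pos = adj$pos, strand = adj$strand,
                      stringsAsFactors = FALSE)
  for (col in setdiff(names(kept), names(added))) {
    added[[col]] <- if (is.character(kept[[col]])) NA_character_
                    else if (is.factor(kept[[col]]))
                      factor(NA, levels = levels(kept[[col]]))
                    else NA
  }
  if (!is.null(added$sanger_only)) added$sanger_only <- TRUE
  if (nrow(kept) == 0L) {
    if (is.null(added$sanger_only)) added$sanger_only <- TRUE
    final <- added
  } else {
    final <- rbind(kept, added[names(kept)])
  }
  o <- order(final$chrom, final$pos, final$strand)
  final <- final[o, , drop = FALSE]
  rownames(final) <- NULL
  list(final = final, sanger_added = added)
}

#' Run the full compendium decision stage
#'
#' Splits threshold-passing consensus sites by database annotation,
#' applies [finalize_annotated()] and [finalize_unannotated()], and merges
#' Sanger-discovered adjacent sites into the unannotated editome.
#'
#' @param sites Consensus data.frame with `annotated` (logical) and
#'   `context` columns already assigned.
#' @param validation Optional validation records.
#' @param bundle Optional annotation bundle (supplies `db_sites` and
#'   `variants` guards for the Sanger merge).
#' @return List of class `"compendium"` with `final_annotated`,
#'   `final_unannotated`, `excluded` (with `reason`), `sanger_added`.
#' @export
build_compendium <- function(sites, validation = NULL, bundle = NULL) {
  ann <- finalize_annotated(sites[sites$annotated, , drop = FALSE])
  una <- finalize_unannotated(sites[!sites$annotated, , drop = FALSE])
  ms <- merge_sanger_discovered(
    una$kept, validation,
    db_sites = if (!is.null(bundle)) bundle$db_sites,
    variants = if (!is.null(bundle)) bundle$variants)
  excluded <- rbind(ann$excluded, una$excluded)
  out <- list(final_annotated = ann$kept,
              final_unannotated = ms$final,
              excluded = excluded,
              sanger_added = ms$sanger_added)
  class(out) <- "compendium"
  out
}

#' @export
print.compendium <- function(x, ...) {
  cat("editome compendium\n")
  cat(sprintf("  final annotated   : %d site(s)\n", nrow(x$final_annotated)))
  cat(sprintf("  final unannotated : %d site(s) (%d Sanger-discovered)\n",
              nrow(x$final_unannotated), nrow(x$sanger_added)))
  if (nrow(x$excluded)) {
    tab <- table(x$excluded$reason)
    cat("  excluded          :",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  } else cat("  excluded          : 0\n")
  invisible(x)
}
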