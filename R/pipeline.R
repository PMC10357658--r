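#' Run the full editome-construction pipeline
#'
#' Executes the stages in their fixed order: read calls, filter against
#' variants/repeats/mappability, build cross-sample cross-method
#' consensus, apply the editing-level and reproducibility thresholds,
#' split by database annotation, classify genomic context, apply the
#' compendium decision rules, and (when validation records are supplied)
#' merge Sanger-discovered adjacent sites.  All outputs are written under
#' `output_dir` together with a JSON run manifest recording the
#' configuration, input digests and per-stage counts; identical inputs
#' and configuration yield byte-identical site tables.
#'
#' @param calls_dir Directory of `<sample>__<method>.tsv` call tables
#'   (see [read_calls_dir()]), or a data.frame of calls.
#' @param bundle An [read_annotation_bundle()] object, or a named list of
#'   paths (`fasta`, `gff3`, `repeats`, `vlincs`, `variants`, `map100`,
#'   `map24`, `db_sites`) to read one from.
#' @param output_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param validation Optional path to a validation TSV (or a parsed
#'   data.frame from [read_validation_records()]).
#' @return Invisibly, a list with `consensus`, `retained`, `compendium`,
#'   `report` (filter report), `context_counts`, `manifest`.
#' @export
run_editome_pipeline <- function(calls_dir, bundle, output_dir,
                                 config = pipeline_config(),
                                 validation = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  input_files <- character()
  if (is.character(calls_dir)) {
    input_files <- list.files(calls_dir, pattern = "\\.tsv$",
                              full.names = TRUE)
    calls <- read_calls_dir(calls_dir)
  } else calls <- calls_dir
  if (is.list(bundle) && !inherits(bundle, "annotation_bundle")) {
    input_files <- c(input_files, unlist(bundle, use.names = FALSE))
    bundle <- read_annotation_bundle(
      bundle$fasta, bundle$gff3, bundle$repeats, bundle$vlincs,
      bundle$variants, bundle$map100, bundle$map24, bundle$db_sites)
  }
  if (is.character(validation)) {
    input_files <- c(input_files, validation)
    validation <- read_validation_records(validation)
  }

  filt <- filter_candidates(calls, bundle, config)
  consensus <- build_consensus(filt$pass)
  thr <- apply_reproducibility_thresholds(consensus, config)
  retained <- thr$retained
  retained$annotated <- match_annotated_db(retained, bundle$db_sites)
  retained$context <- classify_context(retained, bundle)
  comp <- build_compendium(retained, validation, bundle)

  final <- rbind(
    if (nrow(comp$final_annotated))
      cbind(comp$final_annotated, sanger_only = FALSE),
    comp$final_unannotated[names(comp$final_unannotated)])
  if (is.null(final)) final <- comp$final_unannotated
  final$final <- rep(TRUE, nrow(final))
  context_counts <- table(final$context, useNA = "ifany")

  write_site_table(consensus, file.path(output_dir, "consensus.tsv"))
  write_site_table(final, file.path(output_dir, "compendium.tsv"))
  export_sites_bed(final, file.path(output_dir, "compendium.bed"))
  excl <- comp$excluded
  utils::write.table(
    excl[c("chrom", "pos", "strand", "reason")],
    file.path(output_dir, "excluded.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(filt$report, file.path(output_dir,
                                            "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    tool = "editomer",
    version = as.character(utils::packageVersion("editomer")),
    seed = config$rng_seed,
    config = unclass(config),
    inputs = as.list(tools::md5sum(sort(input_files[file.exists(
      input_files)]))),
    counts = list(
      filter = as.list(filt$report),
      consensus_sites = nrow(consensus),
      retained = nrow(retained),
      singleton_or_low = nrow(thr$singleton_or_low),
      annotated = sum(retained$annotated),
      unannotated = sum(!retained$annotated),
      context = as.list(stats::setNames(as.integer(context_counts),
                                        names(context_counts))),
      final_annotated = nrow(comp$final_annotated),
      final_unannotated = nrow(comp$final_unannotated),
      sanger_added = nrow(comp$sanger_added),
      excluded = nrow(comp$excluded)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(consensus = consensus, retained = retained,
                 compendium = comp, final = final, report = filt$report,
                 context_counts = context_counts, manifest = manifest))
}

#' Summarize a pipeline output directory
#'
#' Recomputes the headline numbers from the written tables (not from the
#' manifest): compendium size, genomic-context distribution,
#' method-combination counts, and — when a validation table is given —
#' per-stratum and weighted validation ratios.
#'
#' @param output_dir A [run_editome_pipeline()] output directory.
#' @param validation Optional validation TSV path or data.frame.
#' @return Invisibly, a list with `n_final`, `context_counts`,
#'   `method_counts`, and `validation` (NULL when not supplied).
#' @export
summarize_report <- function(output_dir, validation = NULL) {
  comp_path <- file.path(output_dir, "compendium.tsv")
  if (!file.exists(comp_path))
    stop("no compendium.tsv under ", output_dir,
         "; run run_editome_pipeline() first", call. = FALSE)
  final <- read_site_table(comp_path)
  context_counts <- table(final$context, useNA = "ifany")
  method_counts <- sort(table(final$methods), decreasing = TRUE)
  cat(sprintf("final compendium: %d site(s) (%d annotated, %d unannotated)\n",
              nrow(final), sum(final$annotated, na.rm = TRUE),
              sum(!final$annotated, na.rm = TRUE)))
  cat("genomic context:\n")
  for (lab in names(context_counts))
    cat(sprintf("  %-18s %d\n", lab, context_counts[[lab]]))
  cat("method combinations:\n")
  for (lab in names(method_counts))
    cat(sprintf("  %-28s %d\n",
                ifelse(nzchar(lab), lab, "(sanger-only)"),
                method_counts[[lab]]))
  vr <- NULL
  if (!is.null(validation)) {
    if (is.character(validation))
      validation <- read_validation_records(validation)
    key_final <- .site_key(final$chrom, final$pos, final$strand)
    key_val <- .site_key(validation$chrom, validation$pos,
                         validation$strand)
    tested <- validation[key_val %in% key_final, , drop = FALSE]
    ann <- final$annotated[match(.site_key(tested$chrom, tested$pos,
                                           tested$strand), key_final)]
    ann[is.na(ann)] <- FALSE
    strata <- do.call(rbind, lapply(c(TRUE, FALSE), function(a) {
      t_ <- sum(ann == a)
      if (t_ == 0L) return(NULL)
      data.frame(label = if (a) "annotated" else "unannotated",
                 population = sum(final$annotated %in% a),
                 tested = t_,
                 positive = sum(tested$status[ann == a] == "validated"))
    }))
    vr <- list(strata = strata,
               weighted_ratio = weighted_validation_ratio(strata))
    cat(sprintf("weighted validation ratio: %.1f%%\n",
                100 * vr$weighted_ratio))
  } else {
    cat("validation ratios: not available (no validation table)\n")
  }
  invisible(list(n_final = nrow(final), context_counts = context_counts,
                 method_counts = method_counts, validation = vr))
}
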