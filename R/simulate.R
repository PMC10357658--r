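#' Simulation configuration
#'
#' Parameters of the synthetic editome generator.  The defaults describe
#' the study conditions the pipeline is designed for, scaled to a toy
#' genome: a mostly intronic truth editome with a uracil preference
#' immediately 5' of the edited adenosine, beta-distributed editing
#' levels, three callers with different sensitivities and strongly
#' asymmetric singleton false-positive rates (REDItools emitting an order
#' of magnitude more), recurrent false-positive hotspots seen in several
#' samples, and heterozygous A/G "hidden" SNPs absent from the known
#' variant list that mimic editing in every sample.
#'
#' @param rng_seed Integer seed; the same seed yields byte-identical
#'   output files.
#' @param genome_length Total genome size in bp, split over `n_contigs`.
#' @param n_contigs Number of contigs.
#' @param n_genes Gene count (single-transcript loci, non-overlapping).
#' @param coding_fraction Fraction of genes that are protein-coding; the
#'   rest are lncRNA loci.
#' @param repeat_fraction Approximate fraction of the genome covered by
#'   repeat intervals; half are labelled Alu.
#' @param n_vlincs Number of stranded vlincRNA intervals (placed in
#'   gene-free territory).
#' @param n_samples Number of RNA samples.
#' @param n_true_sites Truth editome size.
#' @param context_weights Named placement weights over the context labels
#'   (must sum to 1).
#' @param p_u_minus1 Probability that the transcript-sense base
#'   immediately 5' of a true site is U.
#' @param level_alpha,level_beta Beta parameters of true editing levels.
#' @param sensitivity Named per-method detection probability of a true
#'   site per sample.
#' @param fp_per_sample Named per-method count of singleton
#'   false-positive calls per sample.
#' @param n_recurrent_fp Number of false-positive hotspot positions that
#'   recur in 2-4 samples.
#' @param hidden_snp_count Heterozygous A/G variants absent from the
#'   emitted variant list; called at level ~0.5 by all methods in all
#'   samples.
#' @param n_listed_variants Known variant positions emitted to the
#'   variant list; half of them also generate SNP-like calls, exercising
#'   the variant filter.
#' @param low_map_patch_fraction Fraction of the genome covered by
#'   low-mappability patches (100mer score 0, 24mer score 0.2).
#' @param annotated_db_fraction Fraction of truth sites marked as present
#'   in the annotated editing database.
#' @param adjacent_fraction Fraction of validated sites that reveal one
#'   additional adjacent site in the Sanger trace.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(rng_seed = 1L,
                       genome_length = 2e6,
                       n_contigs = 2L,
                       n_genes = 60L,
                       coding_fraction = 0.7,
                       repeat_fraction = 0.4,
                       n_vlincs = 8L,
                       n_samples = 12L,
                       n_true_sites = 400L,
                       context_weights = c(
                         CDS = 0.01, UTR5 = 0.02, UTR3 = 0.10,
                         lncRNA_exon = 0.05, intron = 0.66,
                         vlincRNA = 0.04, antisense_exon = 0.03,
                         antisense_intron = 0.03, intergenic = 0.06),
                       p_u_minus1 = 0.5,
                       level_alpha = 2, level_beta = 2,
                       sensitivity = c("REDItools" = 0.6,
                                       "RED-ML" = 0.8,
                                       "SPRINT" = 0.5),
                       fp_per_sample = c("REDItools" = 300L,
                                         "RED-ML" = 30L,
                                         "SPRINT" = 30L),
                       n_recurrent_fp = 20L,
                       hidden_snp_count = 15L,
                       n_listed_variants = 60L,
                       low_map_patch_fraction = 0.05,
                       annotated_db_fraction = 0.5,
                       adjacent_fraction = 0.1) {
  stopifnot(abs(sum(context_weights) - 1) < 1e-8,
            all(context_weights >= 0),
            all(names(context_weights) %in% .CONTEXT_LEVELS),
            p_u_minus1 >= 0, p_u_minus1 <= 1,
            all(sensitivity >= 0 & sensitivity <= 1),
            setequal(names(sensitivity), .DECISION_METHODS),
            setequal(names(fp_per_sample), .DECISION_METHODS),
            repeat_fraction >= 0, repeat_fraction < 1,
            low_map_patch_fraction >= 0, low_map_patch_fraction < 1,
            annotated_db_fraction >= 0, annotated_db_fraction <= 1,
            adjacent_fraction >= 0, adjacent_fraction <= 1,
            n_contigs >= 1, genome_length >= n_contigs * 1e4)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a complete synthetic fixture directory
#'
#' Writes a toy genome with planted gene models, repeats, vlincRNAs,
#' mappability tracks, a known-variant list, an annotated-site database,
#' a truth editome, and one normalized call table per (sample, method) —
#' everything [run_editome_pipeline()] consumes.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List of class `"editome_sim"`: `paths` (named file paths,
#'   `calls_dir` for the call tables), `truth` (truth site table with
#'   `context` and `annotated`), `hidden_snps`, `listed_variants`,
#'   `hotspots` (recurrent false-positive sites), `config`.
#' @examples
#' \donttest{
#' sim <- simulate_editome(sim_config(genome_length = 1e5, n_genes = 6,
#'                                    n_true_sites = 40, n_samples = 4,
#'                                    fp_per_sample = c("REDItools" = 30,
#'                                                      "RED-ML" = 5,
#'                                                      "SPRINT" = 5)),
#'                         tempfile("sim"))
#' head(sim$truth)
#' }
#' @export
simulate_editome <- function(config = sim_config(), dir) {
  truth <- generate_truth(config, dir)
  generate_method_calls(truth, config)
  truth
}

#' Generate the toy genome, annotation bundle and truth editome
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return An `"editome_sim"` object (see [simulate_editome()]); the call
#'   tables are not yet written.
#' @export
generate_truth <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  set.seed(config$rng_seed)
  margin <- 200L

  clen <- rep(floor(config$genome_length / config$n_contigs),
              config$n_contigs)
  contigs <- paste0("chrS", seq_len(config$n_contigs))
  names(clen) <- contigs
  seqs <- lapply(clen, function(n)
    sample(c("A", "C", "G", "T"), n, replace = TRUE))

  genes <- .sim_genes(config, clen)
  vlincs <- .sim_vlincs(config, clen)
  repeats <- .sim_intervals(clen, config$repeat_fraction,
                            width_range = c(150L, 800L))
  repeats$family <- ifelse(stats::runif(nrow(repeats)) < 0.5, "Alu", "L1")
  patches <- .sim_intervals(clen, config$low_map_patch_fraction,
                            width_range = c(200L, 800L))

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    repeats = file.path(dir, "repeats.bed"),
    vlincs = file.path(dir, "vlincs.bed"),
    variants = file.path(dir, "variants.tsv"),
    map100 = file.path(dir, "map100.bedGraph"),
    map24 = file.path(dir, "map24.bedGraph"),
    db_sites = file.path(dir, "db_sites.tsv"),
    truth = file.path(dir, "truth_sites.tsv"),
    calls_dir = file.path(dir, "calls"))

  .write_gff3(genes, paths$gff3)
  .write_bed(repeats, paths$repeats, name = repeats$family)
  .write_bed(vlincs, paths$vlincs, name = sprintf("vlinc%d",
                                                  seq_len(nrow(vlincs))),
             strand = vlincs$strand)
  .write_mappability(patches, clen, paths$map100, patch_score = 0)
  .write_mappability(patches, clen, paths$map24, patch_score = 0.2)
  # preliminary genome + empty variant/db tables so the bundle reader can
  # index the annotation; sequence-dependent pieces are planted next
  .write_fasta(seqs, paths$fasta)
  writeLines("chrom\tpos", paths$variants)
  writeLines("chrom\tpos\tstrand", paths$db_sites)
  bundle <- read_annotation_bundle(
    paths$fasta, paths$gff3, paths$repeats, paths$vlincs, paths$variants,
    paths$map100, paths$map24, paths$db_sites)

  excl <- .exclusion_gr(repeats, patches, clen, margin)
  regions <- .context_regions(bundle, excl, clen, margin)

  weights <- config$context_weights[config$context_weights > 0]
  counts <- .apportion(config$n_true_sites, weights)
  taken <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      stringsAsFactors = FALSE)
  for (lab in names(counts)) {
    if (counts[lab] == 0L) next
    reg <- regions[[lab]]
    if (is.null(reg) || length(reg) == 0L)
      stop("context '", lab, "' demanded by context_weights is absent ",
           "from the toy annotation", call. = FALSE)
    picked <- .sample_positions(reg, counts[lab], taken, spacing = 12L)
    picked$context <- lab
    taken <- rbind(taken, picked)
  }
  truth_sites <- taken

  # plant the edited adenosine and its 5' neighbour in the genome
  for (i in seq_len(nrow(truth_sites))) {
    chrom <- truth_sites$chrom[i]
    pos <- truth_sites$pos[i]
    plus <- truth_sites$strand[i] == "+"
    seqs[[chrom]][pos] <- if (plus) "A" else "T"
    sense_m1 <- if (stats::runif(1) < config$p_u_minus1) "T"
                else sample(c("A", "C", "G"), 1L)
    m1 <- if (plus) pos - 1L else pos + 1L
    seqs[[chrom]][m1] <- if (plus) sense_m1 else chartr("ACGT", "TGCA",
                                                        sense_m1)
  }

  hidden <- .sample_positions(regions$intron, config$hidden_snp_count,
                              truth_sites, spacing = 12L)
  for (i in seq_len(nrow(hidden))) {
    plus <- hidden$strand[i] == "+"
    seqs[[hidden$chrom[i]]][hidden$pos[i]] <- if (plus) "A" else "T"
  }
  .write_fasta(seqs, paths$fasta)

  # listed variants: editable, filter-passing positions away from truth
  pool_excl <- rbind(truth_sites[c("chrom", "pos", "strand")],
                     hidden[c("chrom", "pos", "strand")])
  listed <- .sample_editable(seqs, excl, clen, config$n_listed_variants,
                             pool_excl, margin)
  write.table(listed[c("chrom", "pos")], paths$variants, sep = "\t",
              quote = FALSE, row.names = FALSE)

  n_db <- round(config$annotated_db_fraction * nrow(truth_sites))
  db_idx <- sample(nrow(truth_sites), n_db)
  truth_sites$annotated <- seq_len(nrow(truth_sites)) %in% db_idx
  db <- truth_sites[truth_sites$annotated, c("chrom", "pos", "strand")]
  # a fifth of database records come without strand, as in the mixed
  # strand-reporting of the public databases
  if (nrow(db))
    db$strand[stats::runif(nrow(db)) < 0.2] <- "."
  write.table(db, paths$db_sites, sep = "\t", quote = FALSE,
              row.names = FALSE)
  o <- order(truth_sites$chrom, truth_sites$pos)
  truth_sites <- truth_sites[o, , drop = FALSE]
  rownames(truth_sites) <- NULL
  write.table(truth_sites, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)

  structure(list(paths = paths, truth = truth_sites,
                 hidden_snps = hidden, listed_variants = listed,
                 hotspots = NULL, seqs = seqs, excl = excl,
                 clen = clen, margin = margin, config = config),
            class = "editome_sim")
}

#' Generate the per-sample per-method call tables
#'
#' True sites get one latent beta-distributed editing level per (site,
#' sample); each method detects the site with its configured sensitivity
#' and reports the latent level plus small observation noise.  Singleton
#' false positives land at random editable positions per sample per
#' method; recurrent hotspots recur in 2-4 samples under one method;
#' hidden SNPs and the called half of the listed variants are emitted by
#' all methods in all samples at levels near 0.5.
#'
#' @param sim An `"editome_sim"` object from [generate_truth()].
#' @param config A [sim_config()] (defaults to the one inside `sim`).
#' @return `sim`, with `hotspots` filled in, invisibly.
#' @export
generate_method_calls <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "editome_sim"))
  set.seed(config$rng_seed + 1L)
  truth <- sim$truth
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  methods <- .DECISION_METHODS

  pool_excl <- rbind(truth[c("chrom", "pos", "strand")],
                     sim$hidden_snps[c("chrom", "pos", "strand")],
                     sim$listed_variants[c("chrom", "pos", "strand")])
  n_pool <- sum(config$fp_per_sample) * config$n_samples * 2L +
    config$n_recurrent_fp
  pool <- .sample_editable(sim$seqs, NULL, sim$clen, n_pool, pool_excl,
                           sim$margin)

  hot_idx <- sample(nrow(pool), config$n_recurrent_fp)
  hotspots <- pool[hot_idx, , drop = FALSE]
  pool <- pool[-hot_idx, , drop = FALSE]
  hotspots$method <- sample(methods, nrow(hotspots), replace = TRUE,
                            prob = c(0.6, 0.2, 0.2))

  clamp <- function(x) pmin(pmax(x, 0.01), 0.99)
  latent <- matrix(stats::rbeta(nrow(truth) * config$n_samples,
                                config$level_alpha, config$level_beta),
                   nrow = nrow(truth))

  calls <- vector("list", length(samples) * length(methods))
  k <- 0L
  for (si in seq_along(samples)) {
    for (m in methods) {
      det <- stats::runif(nrow(truth)) < config$sensitivity[[m]]
      tcalls <- data.frame(
        chrom = truth$chrom[det], pos = truth$pos[det],
        strand = truth$strand[det],
        editing_level = clamp(latent[det, si] +
                                stats::rnorm(sum(det), 0, 0.02)),
        coverage = sample(20:200, sum(det), replace = TRUE),
        stringsAsFactors = FALSE)
      nfp <- config$fp_per_sample[[m]]
      fp_idx <- sample(nrow(pool), nfp)
      fcalls <- data.frame(
        chrom = pool$chrom[fp_idx], pos = pool$pos[fp_idx],
        strand = pool$strand[fp_idx],
        editing_level = clamp(stats::rbeta(nfp, config$level_alpha,
                                           config$level_beta)),
        coverage = sample(10:80, nfp, replace = TRUE),
        stringsAsFactors = FALSE)
      snp <- rbind(sim$hidden_snps[c("chrom", "pos", "strand")],
                   sim$listed_variants[sim$listed_variants$called,
                                       c("chrom", "pos", "strand")])
      scalls <- data.frame(
        chrom = snp$chrom, pos = snp$pos, strand = snp$strand,
        editing_level = clamp(stats::rnorm(nrow(snp), 0.5, 0.03)),
        coverage = sample(50:300, nrow(snp), replace = TRUE),
        stringsAsFactors = FALSE)
      hot <- hotspots[hotspots$method == m, , drop = FALSE]
      k <- k + 1L
      calls[[k]] <- list(sample = samples[si], method = m,
                         calls = rbind(tcalls, fcalls, scalls),
                         hot = hot)
    }
  }
  # recurrent hotspots: pick the 2-4 samples per hotspot once
  hot_samples <- lapply(seq_len(nrow(hotspots)), function(i)
    sample(samples, sample(2:4, 1L)))
  for (k in seq_along(calls)) {
    cl <- calls[[k]]
    in_sample <- vapply(seq_len(nrow(hotspots)), function(i)
      hotspots$method[i] == cl$method && cl$sample %in% hot_samples[[i]],
      TRUE)
    if (any(in_sample)) {
      h <- hotspots[in_sample, , drop = FALSE]
      hcalls <- data.frame(
        chrom = h$chrom, pos = h$pos, strand = h$strand,
        editing_level = clamp(stats::rbeta(nrow(h), config$level_alpha,
                                           config$level_beta)),
        coverage = sample(10:80, nrow(h), replace = TRUE),
        stringsAsFactors = FALSE)
      cl$calls <- rbind(cl$calls, hcalls)
    }
    x <- cl$calls
    x <- x[!duplicated(.site_key(x$chrom, x$pos, x$strand)), , drop = FALSE]
    x <- x[order(x$chrom, x$pos, x$strand), , drop = FALSE]
    x$editing_level <- round(x$editing_level, 4)
    f <- file.path(sim$paths$calls_dir,
                   sprintf("%s__%s.tsv", cl$sample, cl$method))
    write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sim$hotspots <- hotspots
  invisible(sim)
}

#' Generate Sanger-style validation outcomes for final sites
#'
#' Truth sites validate (RNA edited, gDNA homozygous reference); hidden
#' SNPs are exposed as sequence variants (the A/G mixture is present in
#' DNA); everything else fails.  A configurable fraction of validated
#' sites reveals one adjacent new site in the trace.
#'
#' @param final_sites Data.frame of sites to test (`chrom`, `pos`,
#'   `strand`).
#' @param sim An `"editome_sim"` object.
#' @param path Output TSV path (defaults to `validation.tsv` next to the
#'   truth table).
#' @param seed RNG seed for the adjacent-site draws.
#' @return The validation data.frame (written to `path`), invisibly.
#' @export
generate_validation_outcomes <- function(final_sites, sim,
                                         path = NULL,
                                         seed = sim$config$rng_seed + 2L) {
  set.seed(seed)
  config <- sim$config
  if (is.null(path))
    path <- file.path(dirname(sim$paths$truth), "validation.tsv")
  truth_keys <- .site_key(sim$truth$chrom, sim$truth$pos, sim$truth$strand)
  snp_keys <- .site_key(sim$hidden_snps$chrom, sim$hidden_snps$pos,
                        sim$hidden_snps$strand)
  keys <- .site_key(final_sites$chrom, final_sites$pos, final_sites$strand)
  is_true <- keys %in% truth_keys
  is_snp <- keys %in% snp_keys
  status <- ifelse(is_true, "validated",
                   ifelse(is_snp, "sequence_variant", "failed"))
  rna <- ifelse(is_true | is_snp, "edited", "not_detected")
  gdna <- ifelse(is_snp, "variant", "homozygous_reference")
  adjacent <- rep("", nrow(final_sites))
  gains <- which(is_true & stats::runif(nrow(final_sites)) <
                   config$adjacent_fraction)
  avoid <- c(keys, .site_key(sim$listed_variants$chrom,
                             sim$listed_variants$pos,
                             sim$listed_variants$strand))
  for (i in gains) {
    off <- sample(c(-3L, 3L), 1L)
    cand <- .site_key(final_sites$chrom[i], final_sites$pos[i] + off,
                      final_sites$strand[i])
    if (cand %in% avoid) next
    adjacent[i] <- sprintf("%s:%d:%s", final_sites$chrom[i],
                           final_sites$pos[i] + off, final_sites$strand[i])
  }
  out <- data.frame(
    chrom = final_sites$chrom, pos = final_sites$pos,
    strand = final_sites$strand,
    tested_sample = sample(sprintf("S%02d", seq_len(config$n_samples)),
                           nrow(final_sites), replace = TRUE),
    rna_outcome = rna, gdna_outcome = gdna, status = status,
    adjacent = adjacent, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

# ---- internal generator helpers -------------------------------------------

# non-overlapping gene loci laid out on a per-contig grid
.sim_genes <- function(config, clen) {
  n_per <- ceiling(config$n_genes / length(clen))
  genes <- list()
  gid <- 0L
  for (chrom in names(clen)) {
    len <- clen[[chrom]]
    usable <- floor(0.80 * len)
    block <- floor(usable / n_per)
    for (i in seq_len(n_per)) {
      if (gid >= config$n_genes) break
      gid <- gid + 1L
      k <- sample(3:7, 1L)
      exon_w <- sample(100:300, k, replace = TRUE)
      intron_w <- sample(300:1500, k - 1L, replace = TRUE)
      span <- sum(exon_w) + sum(intron_w)
      if (span + 20L > block) { # shrink to fit the grid cell
        intron_w <- pmax(300L, floor(intron_w * (block - sum(exon_w) -
                                                   20L) / sum(intron_w)))
        span <- sum(exon_w) + sum(intron_w)
      }
      start <- (i - 1L) * block + sample.int(max(block - span - 10L, 1L), 1L)
      widths <- integer(2L * k - 1L)
      widths[seq(1L, 2L * k - 1L, by = 2L)] <- exon_w
      if (k > 1L) widths[seq(2L, 2L * k - 2L, by = 2L)] <- intron_w
      ends <- start + cumsum(widths) - 1L
      starts <- c(start, utils::head(ends, -1L) + 1L)
      exon_idx <- seq(1L, 2L * k - 1L, by = 2L)
      coding <- stats::runif(1) < config$coding_fraction
      genes[[gid]] <- list(
        chrom = chrom, id = sprintf("gene%03d", gid),
        start = start, end = ends[length(ends)],
        strand = sample(c("+", "-"), 1L),
        coding = coding,
        exon_start = starts[exon_idx], exon_end = ends[exon_idx],
        cds_lo = start + floor(exon_w[1L] / 2),
        cds_hi = ends[length(ends)] - floor(exon_w[k] / 2))
    }
  }
  genes
}

# stranded vlincRNAs in the gene-free tail of each contig
.sim_vlincs <- function(config, clen) {
  n_per <- ceiling(config$n_vlincs / length(clen))
  out <- list()
  for (chrom in names(clen)) {
    len <- clen[[chrom]]
    lo <- ceiling(0.82 * len)
    hi <- floor(0.99 * len)
    slot <- floor((hi - lo) / n_per)
    for (i in seq_len(n_per)) {
      if (length(out) >= config$n_vlincs) break
      s <- lo + (i - 1L) * slot + sample.int(floor(slot * 0.2), 1L)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = s + floor(slot * 0.6),
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# alternating gap/interval walk covering roughly `fraction` of each contig
.sim_intervals <- function(clen, fraction, width_range) {
  if (fraction <= 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  wm <- mean(width_range)
  gm <- wm * (1 / fraction - 1)
  gap_range <- c(max(50L, floor(0.3 * gm)), ceiling(1.7 * gm))
  out <- list()
  for (chrom in names(clen)) {
    pos <- 1L
    len <- clen[[chrom]]
    repeat {
      pos <- pos + sample(gap_range[1]:gap_range[2], 1L)
      w <- sample(width_range[1]:width_range[2], 1L)
      if (pos + w > len) break
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = pos + w - 1L,
        stringsAsFactors = FALSE)
      pos <- pos + w
    }
  }
  do.call(rbind, out)
}

# 1-based inclusive interval data.frame -> GRanges
.df_gr <- function(df, strand = NULL) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         strand = if (is.null(strand)) "*" else strand)
}

# repeat + low-mappability + contig-margin exclusion zone (unstranded)
.exclusion_gr <- function(repeats, patches, clen, margin) {
  edge <- GenomicRanges::GRanges(
    rep(names(clen), each = 2L),
    IRanges::IRanges(
      as.integer(rbind(1L, clen - margin)),
      as.integer(rbind(margin, clen))))
  GenomicRanges::reduce(c(.df_gr(repeats), .df_gr(patches), edge),
                        ignore.strand = TRUE)
}

# mutually exclusive stranded placement regions per context label
.context_regions <- function(bundle, excl, clen, margin) {
  feats <- bundle$features
  ftype <- as.character(feats$type)
  sel <- function(ty) feats[ftype == ty]
  flip <- function(gr) {
    s <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(s == "+", "-", "+")
    gr
  }
  both <- function(gr) {
    g1 <- gr; GenomicRanges::strand(g1) <- "+"
    g2 <- gr; GenomicRanges::strand(g2) <- "-"
    c(g1, g2)
  }
  genome_gr <- GenomicRanges::GRanges(
    names(clen), IRanges::IRanges(1L, as.integer(clen)))
  gene_spans <- GenomicRanges::reduce(GenomicRanges::granges(feats),
                                      ignore.strand = TRUE)
  intergenic <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(genome_gr, gene_spans, ignore.strand = TRUE),
    GenomicRanges::granges(bundle$vlincs), ignore.strand = TRUE)
  regs <- list(
    CDS = sel("CDS"), UTR5 = sel("UTR5"), UTR3 = sel("UTR3"),
    lncRNA_exon = sel("lncRNA_exon"), intron = sel("intron"),
    vlincRNA = GenomicRanges::granges(bundle$vlincs),
    antisense_exon = flip(sel("exon")),
    antisense_intron = flip(sel("intron")),
    intergenic = both(intergenic))
  lapply(regs, function(gr) {
    gr <- GenomicRanges::reduce(gr)
    parts <- lapply(c("+", "-"), function(s) {
      sub <- gr[as.character(GenomicRanges::strand(gr)) %in% c(s, "*")]
      if (!length(sub)) return(NULL)
      GenomicRanges::strand(sub) <- "*"
      d <- GenomicRanges::setdiff(sub, excl, ignore.strand = TRUE)
      GenomicRanges::strand(d) <- s
      d
    })
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (!length(parts)) return(GenomicRanges::GRanges())
    out <- do.call(c, parts)
    out[GenomicRanges::width(out) >= 3L]
  })
}

# width-weighted position sampling with a minimum spacing to prior picks
.sample_positions <- function(regions, n, existing, spacing) {
  picked <- data.frame(chrom = character(), pos = integer(),
                       strand = character(), stringsAsFactors = FALSE)
  widths <- GenomicRanges::width(regions)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  strands <- as.character(GenomicRanges::strand(regions))
  starts <- GenomicRanges::start(regions)
  tries <- 0L
  while (nrow(picked) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n)
      stop("cannot place ", n, " sites with ", spacing,
           "-bp spacing in the available regions", call. = FALSE)
    i <- sample.int(length(regions), 1L, prob = widths)
    pos <- starts[i] + sample.int(widths[i], 1L) - 1L
    near <- c(existing$pos[existing$chrom == chroms[i]],
              picked$pos[picked$chrom == chroms[i]])
    if (length(near) && min(abs(near - pos)) < spacing) next
    strand <- strands[i]
    if (strand == "*") strand <- sample(c("+", "-"), 1L)
    picked <- rbind(picked, data.frame(chrom = chroms[i], pos = pos,
                                       strand = strand,
                                       stringsAsFactors = FALSE))
  }
  picked
}

# positions whose forward base is A (strand '+') or T (strand '-'),
# outside `excl`, away from `avoid` sites; used for variants and FP pools
.sample_editable <- function(seqs, excl, clen, n, avoid, margin) {
  avoid_key <- .pos_key(avoid$chrom, avoid$pos)
  out <- data.frame(chrom = character(), pos = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 200L)
      stop("cannot sample enough editable positions", call. = FALSE)
    m <- 2L * (n - nrow(out)) + 50L
    chrom <- sample(names(clen), m, replace = TRUE,
                    prob = as.numeric(clen))
    pos <- vapply(clen[chrom] - 2L * margin, function(u)
      sample.int(u, 1L), 1L) + margin
    base <- mapply(function(ch, p) seqs[[ch]][p], chrom, pos,
                   USE.NAMES = FALSE)
    ok <- base %in% c("A", "T")
    cand <- data.frame(chrom = chrom[ok], pos = pos[ok],
                       strand = ifelse(base[ok] == "A", "+", "-"),
                       stringsAsFactors = FALSE)
    cand <- cand[!.pos_key(cand$chrom, cand$pos) %in% avoid_key, ,
                 drop = FALSE]
    if (!is.null(excl) && nrow(cand)) {
      hits <- GenomicRanges::findOverlaps(.sites_gr(cand, FALSE), excl,
                                          ignore.strand = TRUE)
      drop <- unique(S4Vectors::queryHits(hits))
      if (length(drop)) cand <- cand[-drop, , drop = FALSE]
    }
    out <- rbind(out, cand)
    out <- out[!duplicated(.pos_key(out$chrom, out$pos)), , drop = FALSE]
  }
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out$called <- seq_len(n) <= ceiling(n / 2)
  out
}

.write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(vapply(seqs, paste0, "", collapse = ""))
  Biostrings::writeXStringSet(ss, path)
}

.write_bed <- function(df, path, name = ".", strand = NULL) {
  if (nrow(df) == 0L) { file.create(path); return(invisible(path)) }
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = name, score = 0L,
                    strand = if (is.null(strand)) "." else strand)
  o <- order(bed$chrom, bed$start)
  utils::write.table(bed[o, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# full-coverage BedGraph: score 1 outside patches, patch_score inside
.write_mappability <- function(patches, clen, path, patch_score) {
  genome_gr <- GenomicRanges::GRanges(
    names(clen), IRanges::IRanges(1L, as.integer(clen)))
  pat <- GenomicRanges::reduce(.df_gr(patches), ignore.strand = TRUE)
  good <- GenomicRanges::setdiff(genome_gr, pat, ignore.strand = TRUE)
  pat$score <- patch_score
  good$score <- 1
  gr <- sort(c(pat, good), ignore.strand = TRUE)
  GenomeInfoDb::seqlengths(gr) <- clen
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

.write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    bt <- if (g$coding) "protein_coding" else "lncRNA"
    tid <- paste0(g$id, ".t1")
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=%s",
              g$chrom, g$start, g$end, g$strand, g$id, bt),
      sprintf(paste0("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t",
                     "ID=%s;Parent=%s;gene_biotype=%s"),
              g$chrom, g$start, g$end, g$strand, tid, g$id, bt),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$chrom, g$exon_start, g$exon_end, g$strand, tid))
    if (g$coding) {
      cs <- pmax(g$exon_start, g$cds_lo)
      ce <- pmin(g$exon_end, g$cds_hi)
      keep <- cs <= ce
      lines <- c(lines,
        sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                g$chrom, cs[keep], ce[keep], g$strand, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# allocate n among weights: floor, then remainders to largest fractions
.apportion <- function(n, weights) {
  w <- weights / sum(weights)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * w - base
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1L
  }
  stats::setNames(as.integer(base), names(weights))
}
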