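# The default-configuration synthetic study, generated once per test run
# and shared by the pipeline, parameter-recovery and acceptance tests.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "editomer-sim-fixture")
      sim <- simulate_editome(sim_config(), dir)
      bundle <- read_annotation_bundle(
        sim$paths$fasta, sim$paths$gff3, sim$paths$repeats,
        sim$paths$vlincs, sim$paths$variants, sim$paths$map100,
        sim$paths$map24, sim$paths$db_sites)
      res <- run_editome_pipeline(sim$paths$calls_dir, bundle,
                                  file.path(dir, "out"))
      cache <<- list(sim = sim, bundle = bundle, res = res,
                     out_dir = file.path(dir, "out"))
    }
    cache
  }
})

site_keys <- function(df) paste(df$chrom, df$pos, df$strand)
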