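#' Pipeline configuration
#'
#' Bundles the thresholds of the editome-construction rules.  The defaults
#' reproduce the published procedure: a site must reach an aggregated
#' editing level strictly above 0.2 in at least one sample, be found in at
#' least two samples, have a 100mer alignability score of 1 at its
#' position, and a mean 24mer alignability strictly above 0.5 over the
#' +/- 150 bp window around it.
#'
#' @param level_threshold Maximum aggregated editing level must exceed this
#'   value (strict inequality).  Default 0.2.
#' @param min_samples Minimum number of samples in which a site must be
#'   called.  Default 2.
#' @param map_window Half-width in bp of the 24mer-alignability window; the
#'   window is inclusive of the site, hence `2 * map_window + 1` positions.
#'   Default 150.
#' @param map100_required Required 100mer alignability score at the site.
#'   Default 1; compared as `>= map100_required - 1e-9` to tolerate
#'   text-float round trips.
#' @param map24_mean_min Mean 24mer alignability over the window must
#'   exceed this value (strict).  Default 0.5.
#' @param motif_halfwidth Half-width in bp of the motif window.  Default 5.
#' @param rng_seed Integer seed recorded in run manifests.
#'
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$level_threshold
#' @export
pipeline_config <- function(level_threshold = 0.2,
                            min_samples = 2L,
                            map_window = 150L,
                            map100_required = 1,
                            map24_mean_min = 0.5,
                            motif_halfwidth = 5L,
                            rng_seed = 1L) {
  stopifnot(level_threshold >= 0, level_threshold <= 1,
            min_samples >= 1, map_window >= 0,
            map100_required >= 0, map100_required <= 1,
            map24_mean_min >= 0, map24_mean_min <= 1,
            motif_halfwidth >= 1)
  structure(list(level_threshold = level_threshold,
                 min_samples = as.integer(min_samples),
                 map_window = as.integer(map_window),
                 map100_required = map100_required,
                 map24_mean_min = map24_mean_min,
                 motif_halfwidth = as.integer(motif_halfwidth),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("editome pipeline configuration\n")
  cat(sprintf("  editing level threshold : > %g (aggregated per sample)\n",
              x$level_threshold))
  cat(sprintf("  reproducibility         : >= %d samples\n", x$min_samples))
  cat(sprintf("  100mer alignability     : score %g at site\n",
              x$map100_required))
  cat(sprintf("  24mer alignability      : mean > %g over +/- %d bp\n",
              x$map24_mean_min, x$map_window))
  cat(sprintf("  motif half-width        : %d bp\n", x$motif_halfwidth))
  cat(sprintf("  rng seed                : %d\n", x$rng_seed))
  invisible(x)
}
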