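#' Analysis parameters for cluster calling and downstream stages
#'
#' Bundles every numeric constant of the analysis in one validated list.
#' Defaults are the canonical values used throughout: a cluster is seeded
#' by at least \code{min_sites_seed} (T)GCATG sites whose first-to-last
#' footprint span is at most \code{window_bp}; further sites strictly
#' closer than \code{extension_bp} to the growing cluster boundary are
#' absorbed; intronic bases within \code{proximal_intron_bp} of the
#' nearest exon are "proximal intron"; repeat-motif enrichment considers
#' clusters with at least \code{enrichment_min_sites} sites extended by
#' \code{enrichment_flank_bp} on both sides and compares against
#' \code{n_background} random sequences; CLIP peaks are retained when
#' log2 fold enrichment is at least \code{peak_min_log2fe} and p-value at
#' most \code{peak_max_p}; stratified isoform tests are called
#' significant below \code{significance_p}.
#'
#' @param window_bp Seed window span in bp (default 500).
#' @param min_sites_seed Minimum motif sites seeding a cluster (default 4).
#' @param extension_bp Strict distance below which a site extends a
#'   cluster, in bp (default 500).
#' @param proximal_intron_bp Intron bases within this distance of an exon
#'   boundary are proximal intron (default 500).
#' @param enrichment_min_sites Minimum sites for a cluster to enter the
#'   repeat-motif enrichment (default 5).
#' @param enrichment_flank_bp Flank added to each side of an enrichment
#'   cluster (default 50).
#' @param n_background Number of random background sequences (default 10000).
#' @param peak_min_log2fe Minimum peak log2 fold enrichment (default 3).
#' @param peak_max_p Maximum peak p-value (default 0.001).
#' @param significance_p Significance level for stratum tests (default 0.01).
#' @param rng_seed Integer seed for all randomized stages, or NULL.
#' @return A list of class \code{rbclust_params}.
#' @examples
#' p <- analysis_params(min_sites_seed = 5)
#' p$window_bp
#' @export
analysis_params <- function(window_bp = 500L,
                            min_sites_seed = 4L,
                            extension_bp = 500L,
                            proximal_intron_bp = 500L,
                            enrichment_min_sites = 5L,
                            enrichment_flank_bp = 50L,
                            n_background = 10000L,
                            peak_min_log2fe = 3,
                            peak_max_p = 0.001,
                            significance_p = 0.01,
                            rng_seed = NULL) {
  p <- list(
    window_bp = as.integer(window_bp),
    min_sites_seed = as.integer(min_sites_seed),
    extension_bp = as.integer(extension_bp),
    proximal_intron_bp = as.integer(proximal_intron_bp),
    enrichment_min_sites = as.integer(enrichment_min_sites),
    enrichment_flank_bp = as.integer(enrichment_flank_bp),
    n_background = as.integer(n_background),
    peak_min_log2fe = as.numeric(peak_min_log2fe),
    peak_max_p = as.numeric(peak_max_p),
    significance_p = as.numeric(significance_p),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  counts <- c("window_bp", "min_sites_seed", "extension_bp",
              "proximal_intron_bp", "enrichment_min_sites")
  for (nm in counts) {
    if (is.na(p[[nm]]) || p[[nm]] <= 0L)
      stop("analysis_params: '", nm, "' must be a positive integer")
  }
  if (p$enrichment_flank_bp < 0L) stop("enrichment_flank_bp must be >= 0")
  if (p$n_background < 0L) stop("n_background must be >= 0")
  if (p$peak_max_p <= 0 || p$peak_max_p > 1)
    stop("peak_max_p must be in (0, 1]")
  if (p$significance_p <= 0 || p$significance_p > 1)
    stop("significance_p must be in (0, 1]")
  class(p) <- "rbclust_params"
  p
}

# run expr with a locally-set RNG seed, restoring global RNG state after;
# a NULL seed leaves the RNG stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
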