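#' Run configuration for the end-to-end pipeline
#'
#' @param fasta Genome FASTA path.
#' @param gff Annotation path.
#' @param dialect "gff3" or "gtf".
#' @param peaks Peak file path (optional).
#' @param peaks_format "bed8" or "narrowPeak".
#' @param expression Isoform TSV path (optional).
#' @param outdir Output directory.
#' @param params \code{\link{analysis_params}}.
#' @param stages Stages to run, subset of scan, classify, overlap,
#'   enrich, isoform_assoc ("classify" is implied by "scan").
#' @param background_mode Background mode for the enrichment stage.
#' @return Validated list of class \code{rbclust_run_config}.
#' @export
run_config <- function(fasta, gff, dialect = "gff3", peaks = NULL,
                       peaks_format = "bed8", expression = NULL,
                       outdir = "rbclust_out",
                       params = analysis_params(),
                       stages = c("scan", "classify", "overlap",
                                  "enrich", "isoform_assoc"),
                       background_mode = "genomic") {
  known <- c("scan", "classify", "overlap", "enrich", "isoform_assoc")
  if (!all(stages %in% known))
    stop("run_config: unknown stage: ",
         paste(setdiff(stages, known), collapse = ", "))
  for (p in c(fasta, gff, peaks, expression)) {
    if (!is.null(p) && !file.exists(p))
      stop("run_config: input does not exist: ", p)
  }
  if ("overlap" %in% stages && is.null(peaks))
    stop("run_config: stage 'overlap' needs a peak file")
  if ("isoform_assoc" %in% stages &&
      (is.null(peaks) || is.null(expression)))
    stop("run_config: stage 'isoform_assoc' needs peaks and expression")
  structure(list(fasta = fasta, gff = gff, dialect = dialect,
                 peaks = peaks, peaks_format = peaks_format,
                 expression = expression, outdir = outdir,
                 params = params, stages = stages,
                 background_mode = background_mode),
            class = "rbclust_run_config")
}

#' Execute the cluster analysis pipeline
#'
#' Runs the requested stages in order (scan -> classify -> overlap ->
#' enrich -> isoform_assoc), logging record counts per stage and
#' writing per-stage TSV/BED/JSON outputs plus a top-level
#' summary.json with the headline tallies (cluster count, genes with
#' clusters, category distribution, strata sizes, test results). On
#' any stage failure the partially written outputs are removed and the
#' error names the stage.
#'
#' @param config \code{\link{run_config}}.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rbclust_run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(config$outdir, name)
    written <<- c(written, p)
    p
  }
  summary <- list()
  stage <- "load"
  tryCatch({
    genome <- read_genome(config$fasta)
    genes <- read_annotation(config$gff, config$dialect)
    message("loaded ", length(genome), " chromosome(s), ",
            length(genes), " gene(s)")
    write_gff3(genes, out("annotation_utrs.gff3"))

    clusters <- NULL
    if (any(c("scan", "classify", "overlap", "enrich",
              "isoform_assoc") %in% config$stages)) {
      stage <- "scan"
      scan <- scan_genome_for_clusters(genes, genome, config$params,
                                       classify = "classify" %in%
                                         config$stages ||
                                         length(config$stages) > 1L)
      clusters <- scan$clusters
      message("scan: ", nrow(clusters), " cluster(s) in ",
              length(scan$genes_with_clusters), " gene(s)")
      write_clusters_bed(clusters, out("clusters.bed"))
      write_clusters_tsv(clusters, out("clusters.tsv"))
      summary$n_clusters <- nrow(clusters)
      summary$n_genes_with_clusters <- length(scan$genes_with_clusters)
      if ("location_class" %in% names(clusters))
        summary$location_class_counts <-
          as.list(location_class_table(clusters))
    }

    strata <- NULL
    if ("overlap" %in% config$stages) {
      stage <- "overlap"
      peaks <- read_peaks(config$peaks, config$params,
                          config$peaks_format)
      assigned <- assign_peaks_to_genes(peaks, genes)
      message("overlap: ", nrow(assigned), " peak-gene assignment(s)")
      strata <- stratify_peaks_on_clusters(assigned, clusters)
      venn <- overlap_gene_sets(strata$genes_with_clusters,
                                strata$genes_with_peaks)
      jsonlite::write_json(venn, out("venn.json"), auto_unbox = TRUE)
      utils::write.table(strata_table(strata), out("strata.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$venn <- venn
      summary$strata_sizes <- as.list(strata$n[
        c("genes_peaks_on_clusters", "genes_peaks_off_clusters",
          "genes_peaks_no_clusters")])
      summary$percent_on_clusters <- strata$percent_on_clusters
    }

    if ("enrich" %in% config$stages) {
      stage <- "enrich"
      enr <- run_motif_enrichment(clusters, genes, genome,
                                  params = config$params,
                                  background_mode =
                                    config$background_mode)
      message("enrich: ", nrow(enr), " motif row(s), median length ",
              attr(enr, "median_length"))
      utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary$n_significant_motifs <- sum(enr$significant)
    }

    if ("isoform_assoc" %in% config$stages) {
      stage <- "isoform_assoc"
      records <- read_isoform_table(config$expression)
      st <- strata_table(strata)
      cmp <- compare_strata(records, st, config$params)
      message("isoform_assoc: ", nrow(cmp$t_test), " t-test pair(s)")
      utils::write.table(cmp$curves, out("isoform_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cmp$summaries, out("isoform_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(chisq = cmp$chisq, t_test = cmp$t_test),
                           out("isoform_tests.json"),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
      summary$isoform_means <- stats::setNames(
        as.list(cmp$summaries$mean_abs_log2fc), cmp$summaries$stratum)
    }

    stage <- "summary"
    jsonlite::write_json(summary, out("summary.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(summary)
  }, error = function(e) {
    unlink(written)
    stop("run_pipeline: stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
}
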