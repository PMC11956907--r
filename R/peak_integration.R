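#' Read CLIP peaks and apply the enrichment/p-value filter
#'
#' Accepts BED6+2 (columns 7-8 = log2 fold enrichment, p-value) or
#' ENCODE narrowPeak (signalValue read as log2 fold enrichment, pValue
#' as -log10 p). Peaks failing
#' log2FE >= \code{peak_min_log2fe} or p > \code{peak_max_p} are dropped
#' (thresholds inclusive: a peak at exactly log2FE 3 and p 0.001 is
#' retained) and the number removed is reported via message().
#'
#' @param path Peak file path (BED coordinates, 0-based half-open).
#' @param params \code{\link{analysis_params}}.
#' @param format "bed8" or "narrowPeak".
#' @return data.frame with columns chrom, start, end (1-based closed),
#'   name, strand, log2_fold_enrichment, p_value.
#' @export
read_peaks <- function(path, params = analysis_params(),
                       format = c("bed8", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_peaks: no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  need <- if (format == "bed8") 8L else 10L
  if (ncol(tab) < need)
    stop("read_peaks: expected at least ", need, " columns, got ",
         ncol(tab))
  if (format == "bed8") {
    lfe <- tab[[7L]]
    pval <- tab[[8L]]
  } else {
    lfe <- tab[[7L]]
    pval <- 10^(-tab[[8L]])
  }
  if (!is.numeric(lfe) || !is.numeric(pval))
    stop("read_peaks: non-numeric enrichment or p-value column")
  if (any(tab[[2L]] >= tab[[3L]]))
    stop("read_peaks: malformed interval (start >= end)")
  peaks <- data.frame(chrom = as.character(tab[[1L]]),
                      start = as.integer(tab[[2L]]) + 1L,
                      end = as.integer(tab[[3L]]),
                      name = as.character(tab[[4L]]),
                      strand = as.character(tab[[6L]]),
                      log2_fold_enrichment = as.numeric(lfe),
                      p_value = as.numeric(pval),
                      stringsAsFactors = FALSE)
  pass <- peaks$log2_fold_enrichment >= params$peak_min_log2fe &
    peaks$p_value <= params$peak_max_p
  message("read_peaks: ", sum(!pass), " of ", nrow(peaks),
          " peaks removed by the log2FE/p filter")
  out <- peaks[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start, peaks$end),
                         strand = peaks$strand)
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    vapply(genes, `[[`, "", "chrom"),
    IRanges::IRanges(
      vapply(genes, function(g) IRanges::start(g$span), 0L),
      vapply(genes, function(g) IRanges::end(g$span), 0L)),
    strand = vapply(genes, `[[`, "", "strand"),
    gene_id = vapply(genes, `[[`, "", "gene_id"))
}

#' Assign peaks to the genes whose spans they intersect
#'
#' Strand-matched by default because CLIP assays are strand-specific; a
#' peak overlapping several (e.g. nested) genes is assigned to each and
#' yields one row per assignment. Intergenic peaks are dropped.
#'
#' @param peaks data.frame from \code{\link{read_peaks}}.
#' @param genes Named list of \code{\link{gene_model}} objects.
#' @param strand_matched Require identical strand (default TRUE).
#' @return The peaks data.frame with a gene_id column, one row per
#'   peak-gene assignment.
#' @export
assign_peaks_to_genes <- function(peaks, genes, strand_matched = TRUE) {
  if (nrow(peaks) == 0L) {
    peaks$gene_id <- character(0)
    return(peaks)
  }
  pg <- peaks_granges(peaks)
  gg <- genes_granges(genes)
  hits <- GenomicRanges::findOverlaps(pg, gg,
                                      ignore.strand = !strand_matched)
  out <- peaks[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- gg$gene_id[S4Vectors::subjectHits(hits)]
  rownames(out) <- NULL
  out
}

#' Venn counts between cluster-bearing and peak-bearing gene sets
#'
#' @param genes_with_clusters,genes_with_peaks Character vectors.
#' @return List with only_clusters, only_peaks, both (disjoint counts).
#' @export
overlap_gene_sets <- function(genes_with_clusters, genes_with_peaks) {
  a <- unique(genes_with_clusters)
  b <- unique(genes_with_peaks)
  both <- length(intersect(a, b))
  list(only_clusters = length(a) - both,
       only_peaks = length(b) - both,
       both = both)
}

#' Stratify peak-bearing genes by whether peaks fall on motif clusters
#'
#' A gene is in the peaks-on-clusters stratum when at least one of its
#' assigned peaks intersects at least one of its clusters by >= 1 bp; a
#' gene with peaks and clusters but no such intersection is
#' peaks-off-clusters; a peak-bearing gene without clusters is
#' peaks-no-clusters. The three strata partition the peak-bearing genes.
#'
#' @param peaks Gene-assigned peaks (\code{\link{assign_peaks_to_genes}}).
#' @param clusters Cluster data.frame (gene-assigned).
#' @return List of class \code{gene_strata} with the gene-id sets, their
#'   sizes and the on-cluster percentage among peak-bearing genes.
#' @export
stratify_peaks_on_clusters <- function(peaks, clusters) {
  genes_with_peaks <- unique(peaks$gene_id)
  genes_with_clusters <- unique(clusters$gene_id)
  on <- character(0)
  if (nrow(peaks) > 0L && nrow(clusters) > 0L) {
    pg <- peaks_granges(peaks)
    cg <- GenomicRanges::GRanges(clusters$chrom,
                                 IRanges::IRanges(clusters$start,
                                                  clusters$end),
                                 strand = clusters$strand)
    hits <- GenomicRanges::findOverlaps(pg, cg, minoverlap = 1L)
    same_gene <- peaks$gene_id[S4Vectors::queryHits(hits)] ==
      clusters$gene_id[S4Vectors::subjectHits(hits)]
    on <- unique(peaks$gene_id[S4Vectors::queryHits(hits)[same_gene]])
  }
  off <- setdiff(intersect(genes_with_peaks, genes_with_clusters), on)
  none <- setdiff(genes_with_peaks, genes_with_clusters)
  out <- list(genes_with_clusters = genes_with_clusters,
              genes_with_peaks = genes_with_peaks,
              genes_peaks_on_clusters = on,
              genes_peaks_off_clusters = off,
              genes_peaks_no_clusters = none)
  out$n <- vapply(out, length, 0L)
  out$percent_on_clusters <-
    if (length(genes_with_peaks) > 0L)
      100 * length(on) / length(genes_with_peaks) else NA_real_
  class(out) <- "gene_strata"
  out
}

#' @export
print.gene_strata <- function(x, ...) {
  cat(sprintf(paste0(
    "<gene_strata> %d genes with peaks: %d on-cluster (%.1f%%), ",
    "%d off-cluster, %d without clusters\n"),
    x$n[["genes_with_peaks"]], x$n[["genes_peaks_on_clusters"]],
    x$percent_on_clusters, x$n[["genes_peaks_off_clusters"]],
    x$n[["genes_peaks_no_clusters"]]))
  invisible(x)
}

#' Turn gene strata into a two-column membership table
#'
#' @param strata A \code{gene_strata} object.
#' @return data.frame with gene_id and stratum columns covering the
#'   peak-bearing genes.
#' @export
strata_table <- function(strata) {
  stopifnot(inherits(strata, "gene_strata"))
  data.frame(
    gene_id = c(strata$genes_peaks_on_clusters,
                strata$genes_peaks_off_clusters,
                strata$genes_peaks_no_clusters),
    stratum = rep(c("peaks_on_clusters", "peaks_off_clusters",
                    "peaks_no_clusters"),
                  c(length(strata$genes_peaks_on_clusters),
                    length(strata$genes_peaks_off_clusters),
                    length(strata$genes_peaks_no_clusters))),
    stringsAsFactors = FALSE)
}
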