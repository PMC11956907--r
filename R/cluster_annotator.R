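REGION_CLASSES <- c("exon", "proximal_intron", "distal_intron",
                    "utr5", "utr3", "mixed")

in_any <- function(pos, ranges) {
  length(ranges) > 0L &&
    any(pos >= IRanges::start(ranges) & pos <= IRanges::end(ranges))
}

#' Classify a genomic position within a gene
#'
#' Base-level taxonomy: a base in any transcript's UTR intervals is utr5
#' or utr3 (UTR labels take precedence over plain exon when transcripts
#' disagree); otherwise a base in the merged exons is exon; intronic
#' bases are proximal_intron when the distance to the nearest merged
#' exon boundary is at most \code{proximal_intron_bp} (the base adjacent
#' to an exon has distance 1), else distal_intron.
#'
#' @param gene A \code{\link{gene_model}}.
#' @param pos 1-based genomic position within the gene span.
#' @param params \code{\link{analysis_params}}.
#' @return One of "utr5", "utr3", "exon", "proximal_intron",
#'   "distal_intron".
#' @export
classify_position <- function(gene, pos, params = analysis_params()) {
  stopifnot(inherits(gene, "gene_model"))
  if (pos < IRanges::start(gene$span) || pos > IRanges::end(gene$span))
    stop("classify_position: position ", pos, " outside gene ",
         gene$gene_id)
  for (tx in gene$transcripts) {
    if (in_any(pos, tx$utr5)) return("utr5")
  }
  for (tx in gene$transcripts) {
    if (in_any(pos, tx$utr3)) return("utr3")
  }
  if (in_any(pos, gene$merged_exons)) return("exon")
  # intronic: distance in bases to the nearest exon edge
  d_left <- pos - IRanges::end(gene$merged_exons)
  d_right <- IRanges::start(gene$merged_exons) - pos
  d <- min(c(d_left[d_left > 0L], d_right[d_right > 0L]))
  if (d <= params$proximal_intron_bp) "proximal_intron" else "distal_intron"
}

#' Assign a cluster one of the six genomic-context categories
#'
#' Each member site's position is classified with
#' \code{\link{classify_position}}; if all sites agree the cluster takes
#' that class, otherwise it is "mixed". Voting is over member sites, not
#' the full cluster span, so a long extended cluster bridging a short
#' exon while all its motifs sit in introns is still intronic.
#'
#' @param cluster One-row cluster data.frame (with site_starts list
#'   column) from \code{\link{call_clusters}}.
#' @param gene The owning \code{\link{gene_model}}.
#' @param params \code{\link{analysis_params}}.
#' @return A single region class string.
#' @export
classify_cluster <- function(cluster, gene, params = analysis_params()) {
  stopifnot(nrow(cluster) == 1L)
  if (cluster$gene_id != gene$gene_id)
    stop("classify_cluster: cluster does not belong to gene ",
         gene$gene_id)
  pos <- cluster$site_starts[[1L]]
  classes <- unique(vapply(pos, function(p)
    classify_position(gene, p, params), character(1)))
  if (length(classes) == 1L) classes else "mixed"
}

#' Tabulate cluster counts per genomic-context category
#'
#' @param clusters Cluster data.frame with a location_class column.
#' @return Named integer vector over all six categories (zeros kept).
#' @export
location_class_table <- function(clusters) {
  tab <- table(factor(clusters$location_class, levels = REGION_CLASSES))
  stats::setNames(as.integer(tab), names(tab))
}
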