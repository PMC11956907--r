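MOTIF <- "GCATG"
MOTIF_LEN <- 5L

#' Find (T)GCATG motif sites on a gene's sense strand
#'
#' Scans the transcribed strand of the gene span for every occurrence of
#' the pentamer GCATG (overlapping occurrences all count) and records
#' whether the strand-correct preceding base is a T, i.e. whether the
#' site is the hexamer TGCATG. Coordinates returned are genomic (1-based
#' leftmost base of the 5-mer footprint regardless of strand).
#'
#' @param gene A \code{\link{gene_model}}.
#' @param genome DNAStringSet from \code{\link{read_genome}}.
#' @return A data.frame with columns chrom, start, end, strand,
#'   leading_T, gene_id, sorted by genomic start.
#' @export
scan_motifs <- function(gene, genome) {
  stopifnot(inherits(gene, "gene_model"))
  if (!gene$chrom %in% names(genome))
    stop("scan_motifs: chromosome ", gene$chrom, " not in genome")
  chrom_len <- length(genome[[gene$chrom]])
  lo <- IRanges::start(gene$span)
  hi <- IRanges::end(gene$span)
  if (lo < 1L || hi > chrom_len)
    stop("scan_motifs: gene ", gene$gene_id, " span exceeds chromosome ",
         gene$chrom)
  sense <- Biostrings::DNAString(
    genome_subseq(genome, gene$chrom, lo, hi, gene$strand))
  hits <- Biostrings::matchPattern(MOTIF, sense)
  pos_tx <- Biostrings::start(hits)  # 1-based along the transcribed strand
  if (length(pos_tx) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      leading_T = logical(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  if (gene$strand == "+") {
    gstart <- lo + pos_tx - 1L
    # preceding base on the genome, if any
    prev_ok <- gstart > 1L
    prev <- rep(NA_character_, length(gstart))
    if (any(prev_ok)) {
      prev[prev_ok] <- vapply(gstart[prev_ok], function(s)
        genome_subseq(genome, gene$chrom, s - 1L, s - 1L, "+"),
        character(1))
    }
    leading <- !is.na(prev) & prev == "T"
  } else {
    # transcribed position p occupies genomic [hi - p - 3, hi - p + 1]
    gstart <- hi - pos_tx - (MOTIF_LEN - 2L)
    # preceding (5') base on the minus strand sits at genomic gstart+5
    nxt_ok <- gstart + MOTIF_LEN <= chrom_len
    nxt <- rep(NA_character_, length(gstart))
    if (any(nxt_ok)) {
      nxt[nxt_ok] <- vapply(gstart[nxt_ok], function(s)
        genome_subseq(genome, gene$chrom, s + MOTIF_LEN, s + MOTIF_LEN, "+"),
        character(1))
    }
    leading <- !is.na(nxt) & nxt == "A"  # complement of T
  }
  out <- data.frame(chrom = gene$chrom, start = as.integer(gstart),
                    end = as.integer(gstart) + MOTIF_LEN - 1L,
                    strand = gene$strand, leading_T = leading,
                    gene_id = gene$gene_id, stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_clusters <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), gene_id = character(0),
             n_sites = integer(0), n_hexamer_sites = integer(0),
             site_starts = I(list()), stringsAsFactors = FALSE)
}

#' Call (T)GCATG clusters by seed-and-extend-and-merge
#'
#' A cluster is seeded wherever at least \code{min_sites_seed}
#' consecutive sites have a first-to-last footprint span of at most
#' \code{window_bp} bases (inclusive). Any further site whose footprint
#' gap to the growing cluster boundary is strictly less than
#' \code{extension_bp} is absorbed, newly absorbed sites recruit further
#' sites, and overlapping clusters merge, iterated to a fixpoint. On a
#' sorted site list this is equivalent to: chain consecutive sites whose
#' inter-footprint gap is below \code{extension_bp} and keep every chain
#' containing at least one seed window; the package uses that linear
#' characterization, and the test suite checks it against a literal
#' fixpoint iteration.
#'
#' @param sites data.frame from \code{\link{scan_motifs}} (one gene,
#'   sorted by start).
#' @param params \code{\link{analysis_params}}.
#' @return data.frame with one row per cluster: chrom, start, end
#'   (footprint-inclusive genomic interval), strand, gene_id, n_sites,
#'   n_hexamer_sites, and a list column site_starts.
#' @export
call_clusters <- function(sites, params = analysis_params()) {
  if (nrow(sites) == 0L) return(empty_clusters())
  if (length(unique(sites$gene_id)) > 1L)
    stop("call_clusters: sites from multiple genes")
  if (is.unsorted(sites$start))
    stop("call_clusters: sites must be sorted by start")
  s <- sites$start
  e <- sites$end
  n <- length(s)
  m <- params$min_sites_seed
  # chains: consecutive sites with footprint gap < extension_bp
  gap <- s[-1L] - e[-n] - 1L
  chain_id <- cumsum(c(1L, as.integer(gap >= params$extension_bp)))
  keep <- logical(n)
  for (cid in unique(chain_id)) {
    idx <- which(chain_id == cid)
    k <- length(idx)
    if (k < m) next
    # seed: any m consecutive sites with footprint span <= window_bp
    spans <- e[idx[m:k]] - s[idx[1:(k - m + 1L)]] + 1L
    if (any(spans <= params$window_bp)) keep[idx] <- TRUE
  }
  if (!any(keep)) return(empty_clusters())
  kept_chain <- chain_id[keep]
  cl <- lapply(unique(kept_chain), function(cid) {
    idx <- which(chain_id == cid & keep)
    data.frame(chrom = sites$chrom[idx[1L]],
               start = s[idx[1L]], end = e[idx[length(idx)]],
               strand = sites$strand[idx[1L]],
               gene_id = sites$gene_id[idx[1L]],
               n_sites = length(idx),
               n_hexamer_sites = sum(sites$leading_T[idx]),
               site_starts = I(list(s[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cl)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan all genes of a genome for motif clusters
#'
#' Runs \code{\link{scan_motifs}} and \code{\link{call_clusters}} per
#' gene and optionally classifies each cluster's genomic context.
#'
#' @param genes Named list of \code{\link{gene_model}} objects.
#' @param genome DNAStringSet.
#' @param params \code{\link{analysis_params}}.
#' @param classify Add a location_class column (default TRUE).
#' @return A list with elements \code{clusters} (data.frame over all
#'   genes, with cluster_id gene:index) and \code{genes_with_clusters}
#'   (character vector).
#' @export
scan_genome_for_clusters <- function(genes, genome,
                                     params = analysis_params(),
                                     classify = TRUE) {
  res <- lapply(genes, function(g) {
    cl <- call_clusters(scan_motifs(g, genome), params)
    if (nrow(cl) > 0L) {
      cl$cluster_id <- paste0(g$gene_id, ":", seq_len(nrow(cl)))
      if (classify) {
        cl$location_class <- vapply(seq_len(nrow(cl)), function(i)
          classify_cluster(cl[i, ], g, params), character(1))
      }
    }
    cl
  })
  clusters <- do.call(rbind, res[vapply(res, nrow, 0L) > 0L])
  if (is.null(clusters)) {
    clusters <- empty_clusters()
    clusters$cluster_id <- character(0)
    if (classify) clusters$location_class <- character(0)
  }
  rownames(clusters) <- NULL
  list(clusters = clusters,
       genes_with_clusters = unique(clusters$gene_id))
}

#' Write clusters as BED6 (plus a TSV companion)
#'
#' BED is written in its native 0-based half-open convention; name is
#' the cluster_id and score the number of member sites.
#'
#' @param clusters Cluster data.frame.
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
write_clusters_bed <- function(clusters, path) {
  bed <- data.frame(chrom = clusters$chrom,
                    start = clusters$start - 1L,
                    end = clusters$end,
                    name = if ("cluster_id" %in% names(clusters))
                      clusters$cluster_id else
                        paste0(clusters$gene_id, ":", seq_len(nrow(clusters))),
                    score = clusters$n_sites,
                    strand = clusters$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write clusters as a TSV table
#' @param clusters Cluster data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_clusters_tsv <- function(clusters, path) {
  cols <- intersect(c("chrom", "start", "end", "strand", "gene_id",
                      "cluster_id", "n_sites", "n_hexamer_sites",
                      "location_class"), names(clusters))
  utils::write.table(clusters[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
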