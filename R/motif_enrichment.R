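HNRNP_M_PENTAMERS <- c("TGTTG", "GTGTT", "TTGTG", "GTTGT", "TGTGT",
                       "TGGTT", "TTGGT", "GTGTG", "GGTGT", "TGTGG",
                       "GTGGT", "GTTGG", "TGGTG", "GGTTG")
HNRNP_H_PENTAMERS <- c("GGGGT", "GGGGG", "CGGGG", "AGGGG", "TGGGG",
                       "GGGGC", "GGGGA")
HNRNP_C_PENTAMERS <- c("ATTTT", "GTTTT", "CTTTT", "TTTTA", "TTTTC",
                       "TTTTG", "TTTTT")

#' Enumerate all (TG/CA)6 repeat 12-mers
#'
#' Every concatenation of six dinucleotide units, each TG or CA: 64
#' distinct sequences, sorted.
#'
#' @return Character vector of length 64.
#' @export
enumerate_tgca_repeats <- function() {
  units <- expand.grid(rep(list(c("TG", "CA")), 6L),
                       stringsAsFactors = FALSE)
  sort(unique(apply(units, 1L, paste0, collapse = "")))
}

#' LASR-associated motif sets
#'
#' The GU-rich hnRNP-M pentamers (14), polyG-rich hnRNP-H pentamers (7),
#' polyU-rich hnRNP-C pentamers (7), written as DNA, and the 64
#' (TG/CA)6 repeat 12-mers.
#'
#' @param name One of "hnRNP-M", "hnRNP-H", "hnRNP-C", "TGCA6".
#' @return List with elements name and motifs (distinct, one common
#'   length).
#' @export
motif_set <- function(name = c("hnRNP-M", "hnRNP-H", "hnRNP-C", "TGCA6")) {
  name <- match.arg(name)
  motifs <- switch(name,
                   "hnRNP-M" = HNRNP_M_PENTAMERS,
                   "hnRNP-H" = HNRNP_H_PENTAMERS,
                   "hnRNP-C" = HNRNP_C_PENTAMERS,
                   "TGCA6" = enumerate_tgca_repeats())
  stopifnot(!anyDuplicated(motifs),
            length(unique(nchar(motifs))) == 1L)
  list(name = name, motifs = motifs)
}

#' Select clusters for repeat-motif enrichment and extract sequences
#'
#' Keeps clusters with at least \code{enrichment_min_sites} member
#' sites, extends each interval by \code{enrichment_flank_bp} on both
#' sides (clipped at chromosome bounds) and extracts the strand-correct
#' sequence.
#'
#' @param clusters Cluster data.frame.
#' @param genome DNAStringSet.
#' @param params \code{\link{analysis_params}}.
#' @return Character vector of sequences, named by cluster_id when
#'   available.
#' @export
select_enrichment_clusters <- function(clusters, genome,
                                       params = analysis_params()) {
  keep <- clusters$n_sites >= params$enrichment_min_sites
  cl <- clusters[keep, , drop = FALSE]
  if (nrow(cl) == 0L) return(character(0))
  n_clipped <- 0L
  seqs <- vapply(seq_len(nrow(cl)), function(i) {
    len <- length(genome[[cl$chrom[i]]])
    lo <- cl$start[i] - params$enrichment_flank_bp
    hi <- cl$end[i] + params$enrichment_flank_bp
    if (lo < 1L || hi > len) n_clipped <<- n_clipped + 1L
    genome_subseq(genome, cl$chrom[i], max(1L, lo), min(len, hi),
                  cl$strand[i])
  }, character(1))
  if (n_clipped > 0L)
    message("select_enrichment_clusters: ", n_clipped,
            " flank(s) clipped at chromosome bounds")
  if ("cluster_id" %in% names(cl)) names(seqs) <- cl$cluster_id
  seqs
}

#' Count motif occurrences in a sequence set
#'
#' Exhaustive sliding-window matching; overlapping occurrences all
#' count. Opportunities are the number of window positions,
#' sum(len - k + 1) over sequences at least k long.
#'
#' @param sequences Character vector of uppercase DNA sequences.
#' @param motifs Character vector of same-length motifs (or a
#'   \code{\link{motif_set}}).
#' @return List with counts (named integer vector) and opportunities.
#' @export
count_motif_occurrences <- function(sequences, motifs) {
  if (is.list(motifs)) motifs <- motifs$motifs
  k <- unique(nchar(motifs))
  stopifnot(length(k) == 1L)
  if (length(sequences) == 0L) {
    return(list(counts = stats::setNames(integer(length(motifs)), motifs),
                opportunities = 0L))
  }
  subject <- Biostrings::DNAStringSet(sequences)
  counts <- vapply(motifs, function(m)
    sum(Biostrings::vcountPattern(m, subject)), integer(1))
  opp <- sum(pmax(Biostrings::width(subject) - k + 1L, 0L))
  list(counts = counts, opportunities = as.integer(opp))
}

#' Build randomized background sequences
#'
#' Default mode "genomic" samples fixed-length windows uniformly from
#' the intron space of the supplied gene models (position uniform over
#' all placements, strand uniform), preserving the genome's local
#' composition. Mode "iid" draws independent nucleotides at a configured
#' GC content. Fully reproducible from \code{seed}.
#'
#' @param genes Named list of \code{\link{gene_model}} objects (genomic
#'   mode).
#' @param genome DNAStringSet (genomic mode).
#' @param n Number of sequences.
#' @param length Sequence length in bp (typically the median
#'   flank-extended cluster length).
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @param mode "genomic" or "iid".
#' @param gc_content GC fraction for mode "iid" (default 0.4).
#' @return Character vector of n sequences, each nchar == length.
#' @export
build_background <- function(genes = NULL, genome = NULL, n, length,
                             seed = NULL, mode = c("genomic", "iid"),
                             gc_content = 0.4) {
  mode <- match.arg(mode)
  stopifnot(length >= 1L)
  if (n == 0L) return(character(0))
  with_seed(seed, {
    if (mode == "iid") {
      p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
      big <- paste0(sample(names(p), n * length, replace = TRUE,
                           prob = p), collapse = "")
      starts <- seq.int(1L, by = length, length.out = n)
      substring(big, starts, starts + length - 1L)
    } else {
      stopifnot(!is.null(genes), !is.null(genome))
      pool <- do.call(rbind, lapply(genes, function(g) {
        intr <- g$introns
        keep <- IRanges::width(intr) >= length
        if (!any(keep)) return(NULL)
        data.frame(chrom = g$chrom,
                   start = IRanges::start(intr)[keep],
                   end = IRanges::end(intr)[keep],
                   stringsAsFactors = FALSE)
      }))
      if (is.null(pool) || nrow(pool) == 0L)
        stop("build_background: no intron long enough to place a ",
             length, " bp sequence")
      placements <- pool$end - pool$start - length + 2L
      iv <- sample.int(nrow(pool), n, replace = TRUE,
                       prob = placements)
      off <- floor(stats::runif(n) * placements[iv])
      strand <- sample(c("+", "-"), n, replace = TRUE)
      vapply(seq_len(n), function(i) {
        s <- pool$start[iv[i]] + off[i]
        genome_subseq(genome, pool$chrom[iv[i]], s, s + length - 1L,
                      strand[i])
      }, character(1))
    }
  })
}

#' Chi-square enrichment of motif frequencies, foreground vs background
#'
#' Per motif, occurrence counts are compared over sliding-window
#' opportunities in a 2x2 table [[count_fg, opp_fg - count_fg],
#' [count_bg, opp_bg - count_bg]] with a Pearson chi-square test
#' (no continuity correction). The log2 fold change of per-opportunity
#' frequencies gets a 0.5 pseudocount on zero counts only (never in the
#' test), keeping volcano coordinates finite. P-values are
#' Benjamini-Hochberg adjusted across the motifs supplied (one motif
#' set at a time).
#'
#' @param fg_counts,bg_counts Named integer vectors over the same
#'   motifs.
#' @param fg_opportunities,bg_opportunities Positive totals of window
#'   positions.
#' @param set_name Optional label copied to the output.
#' @param significance_fdr FDR threshold for the significant flag
#'   (default 0.01).
#' @return data.frame with one row per motif: motif, set, count_fg,
#'   count_bg, opp_fg, opp_bg, log2_fold_change, p_value, fdr,
#'   significant.
#' @export
enrichment_test <- function(fg_counts, bg_counts, fg_opportunities,
                            bg_opportunities, set_name = NA_character_,
                            significance_fdr = 0.01) {
  stopifnot(fg_opportunities > 0L, bg_opportunities > 0L,
            length(fg_counts) == length(bg_counts))
  motifs <- names(fg_counts)
  if (!is.null(names(bg_counts)) && !identical(motifs, names(bg_counts)))
    bg_counts <- bg_counts[motifs]
  pvals <- vapply(seq_along(fg_counts), function(i) {
    tab <- matrix(c(fg_counts[i], fg_opportunities - fg_counts[i],
                    bg_counts[i], bg_opportunities - bg_counts[i]),
                  nrow = 2L, byrow = TRUE)
    if (any(tab < 0)) stop("enrichment_test: count exceeds opportunities")
    if (sum(tab[, 1L]) == 0L) return(1)  # motif absent everywhere
    suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  fg <- as.numeric(fg_counts)
  bg <- as.numeric(bg_counts)
  zero <- fg == 0 | bg == 0
  fg[zero] <- fg[zero] + 0.5
  bg[zero] <- bg[zero] + 0.5
  log2fc <- log2((fg / fg_opportunities) / (bg / bg_opportunities))
  fdr <- stats::p.adjust(pvals, method = "BH")
  data.frame(motif = motifs, set = set_name,
             count_fg = as.integer(fg_counts),
             count_bg = as.integer(bg_counts),
             opp_fg = as.integer(fg_opportunities),
             opp_bg = as.integer(bg_opportunities),
             log2_fold_change = log2fc, p_value = pvals, fdr = fdr,
             significant = fdr <= significance_fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full repeat-motif enrichment over one or more motif sets
#'
#' Selects >= \code{enrichment_min_sites}-site clusters extended by the
#' flank, draws \code{n_background} background sequences with length
#' equal to the median foreground sequence length, counts each motif
#' set in both and tests enrichment.
#'
#' @param clusters Cluster data.frame.
#' @param genes Gene models (background sampling).
#' @param genome DNAStringSet.
#' @param sets Character vector of \code{\link{motif_set}} names.
#' @param params \code{\link{analysis_params}}.
#' @param background_mode "genomic" or "iid".
#' @return data.frame of \code{\link{enrichment_test}} rows over all
#'   sets, with attribute "median_length".
#' @export
run_motif_enrichment <- function(clusters, genes, genome,
                                 sets = c("hnRNP-M", "hnRNP-H",
                                          "hnRNP-C", "TGCA6"),
                                 params = analysis_params(),
                                 background_mode = "genomic") {
  fg <- select_enrichment_clusters(clusters, genome, params)
  if (length(fg) == 0L)
    stop("run_motif_enrichment: no cluster passes the ",
         params$enrichment_min_sites, "-site threshold")
  med_len <- as.integer(round(stats::median(nchar(fg))))
  bg <- build_background(genes, genome, n = params$n_background,
                         length = med_len, seed = params$rng_seed,
                         mode = background_mode)
  res <- lapply(sets, function(s) {
    ms <- motif_set(s)
    cf <- count_motif_occurrences(fg, ms)
    cb <- count_motif_occurrences(bg, ms)
    enrichment_test(cf$counts, cb$counts, cf$opportunities,
                    cb$opportunities, set_name = s,
                    significance_fdr = params$significance_p)
  })
  out <- do.call(rbind, res)
  attr(out, "median_length") <- med_len
  out
}
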