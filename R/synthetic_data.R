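#' Configuration for the synthetic fixture generator
#'
#' Describes a small cohort of genes with the long-intron geometry of
#' the canonical TrkB-like test gene: a handful of short exons separated
#' by ~50 kb introns, planted mid-intron motif clusters, background
#' (T)GCATG occurrences at a configurable per-bp rate, CLIP-like peaks
#' preferentially placed on a configurable fraction of clusters, and
#' isoform log2 fold-change tables with stratum-specific effects.
#'
#' @param rng_seed Integer seed driving every random choice.
#' @param n_genes Number of genes (one per chromosome).
#' @param exon_lengths Exon lengths in bp, shared by all genes.
#' @param intron_lengths Intron lengths in bp (length(exon_lengths)-1).
#' @param intergenic_bp Padding around each gene on its chromosome.
#' @param gc_content Background GC fraction.
#' @param background_motif_rate Expected spurious GCATG per sense-strand
#'   bp (0 = clean background; natural occurrences are scrubbed first
#'   and spurious sites re-injected at this rate).
#' @param leading_t_fraction Fraction of injected sites written as the
#'   hexamer TGCATG.
#' @param minus_strand_fraction Fraction of genes placed on "-".
#' @param planted_clusters data.frame with columns gene (index), intron
#'   (index), n_sites, span_bp; NULL plants nothing.
#' @param peak_on_cluster_fraction Fraction of cluster-bearing genes
#'   whose peak lands on a cluster (count rounded, assignment seeded).
#' @param peak_width Peak width in bp.
#' @param n_decoy_peaks Peaks failing the log2FE/p filter, for filter
#'   tests.
#' @param stratum_effects Named list over the three strata, each
#'   c(mean, sd) of the per-gene |log2FC| of the differential isoform.
#' @param isoforms_per_gene Candidate isoform counts per gene.
#' @return List of class \code{rbclust_sim_config}.
#' @export
simulation_config <- function(rng_seed = 1L,
                              n_genes = 6L,
                              exon_lengths = c(300L, 150L, 300L),
                              intron_lengths = c(50000L, 50000L),
                              intergenic_bp = 1000L,
                              gc_content = 0.4,
                              background_motif_rate = 0,
                              leading_t_fraction = 0.8,
                              minus_strand_fraction = 0.5,
                              planted_clusters = NULL,
                              peak_on_cluster_fraction = 0.25,
                              peak_width = 100L,
                              n_decoy_peaks = 4L,
                              stratum_effects = list(
                                peaks_on_clusters = c(mean = 1.8, sd = 0.5),
                                peaks_off_clusters = c(mean = 1.55, sd = 0.5),
                                peaks_no_clusters = c(mean = 1.4, sd = 0.5)),
                              isoforms_per_gene = 2:4) {
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L,
            gc_content >= 0, gc_content <= 1,
            background_motif_rate >= 0, background_motif_rate <= 1,
            leading_t_fraction >= 0, leading_t_fraction <= 1,
            peak_on_cluster_fraction >= 0, peak_on_cluster_fraction <= 1)
  if (!is.null(planted_clusters)) {
    need <- c("gene", "intron", "n_sites", "span_bp")
    stopifnot(all(need %in% names(planted_clusters)))
    bad <- planted_clusters$span_bp <
      7L * (planted_clusters$n_sites - 1L) + 6L
    if (any(bad))
      stop("simulation_config: span_bp too small for n_sites in row ",
           which(bad)[1L])
  }
  structure(as.list(environment()), class = "rbclust_sim_config")
}

#' Planted-cluster specification helper
#' @param gene Gene index.
#' @param intron Intron index within the gene.
#' @param n_sites Number of (T)GCATG sites.
#' @param span_bp Footprint span of the planted cluster.
#' @return One-row data.frame usable in \code{planted_clusters}.
#' @export
plant_spec <- function(gene, intron, n_sites, span_bp = 450L) {
  data.frame(gene = gene, intron = intron, n_sites = n_sites,
             span_bp = span_bp)
}

random_dna <- function(n, gc) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# remove every sense-strand GCATG inside [lo, hi] of a chromosome
# string by mutating the motif's middle base; the replacement base is
# chosen so no new occurrence can be created at that position
scrub_motifs <- function(chrom_seq, lo, hi, strand) {
  repeat {
    sense <- Biostrings::DNAString(substr(chrom_seq, lo, hi))
    if (strand == "-") sense <- Biostrings::reverseComplement(sense)
    pos <- Biostrings::start(Biostrings::matchPattern(MOTIF, sense))
    if (length(pos) == 0L) return(chrom_seq)
    for (p in pos) {
      if (strand == "+") {
        g <- lo + p - 1L + 2L          # middle base (the A)
        substr(chrom_seq, g, g) <- "C"
      } else {
        g <- hi - p + 1L - 2L          # middle base on the genome (a T)
        substr(chrom_seq, g, g) <- "G"
      }
    }
  }
}

# after injection, remove occurrences the generator did not intend:
# writing a motif can complete a second, overlapping occurrence with
# flanking random bases. Mutates one base of each unintended
# occurrence (never touching an intended footprint or its leading-T
# base) and rescans to a fixpoint, so the sites present are exactly
# the intended ones.
enforce_sites <- function(chrom_seq, lo, hi, strand, intended) {
  protected <- IRanges::IRanges(intended - 1L, intended + 5L)
  for (iter in seq_len(25L)) {
    sense <- Biostrings::DNAString(substr(chrom_seq, lo, hi))
    if (strand == "-") sense <- Biostrings::reverseComplement(sense)
    pos <- Biostrings::start(Biostrings::matchPattern(MOTIF, sense))
    gstart <- if (strand == "+") lo + pos - 1L else hi - pos - 3L
    extra <- setdiff(gstart, intended)
    if (length(extra) == 0L) return(chrom_seq)
    for (e in extra) {
      cand <- e:(e + 4L)
      free <- cand[IRanges::countOverlaps(
        IRanges::IRanges(cand, cand), protected) == 0L]
      b <- if (length(free) > 0L)
        free[which.min(abs(free - (e + 2L)))] else e + 2L
      cur <- substr(chrom_seq, b, b)
      substr(chrom_seq, b, b) <- if (cur == "C") "G" else "C"
    }
  }
  stop("enforce_sites: could not stabilize injected motif sites")
}

# write a motif occurrence (sense orientation) at genomic start g
inject_motif <- function(chrom_seq, g, strand, leading_t) {
  if (strand == "+") {
    substr(chrom_seq, g, g + 4L) <- MOTIF
    if (leading_t && g > 1L) substr(chrom_seq, g - 1L, g - 1L) <- "T"
  } else {
    substr(chrom_seq, g, g + 4L) <- "CATGC"
    if (leading_t && g + 5L <= nchar(chrom_seq))
      substr(chrom_seq, g + 5L, g + 5L) <- "A"
  }
  chrom_seq
}

#' Simulate a genome, annotation and motif ground truth
#'
#' Each gene sits on its own chromosome: i.i.d. background sequence at
#' the configured GC, natural sense-strand GCATG occurrences scrubbed,
#' spurious sites re-injected at \code{background_motif_rate}, and the
#' configured clusters planted mid-intron with evenly spaced sites.
#' Occurrences that injection itself would create by completing a
#' motif with flanking bases are removed, so the sense-strand sites
#' present are exactly the planted and rate-driven ones. Ground truth
#' records the planted cluster coordinates and, by a post-scan with
#' the package's own scanner, every motif site present.
#'
#' @param config \code{\link{simulation_config}}.
#' @return List with genome (DNAStringSet), genes (gene_model list),
#'   truth (planted, sites, background_sites) and config.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "rbclust_sim_config"))
  with_seed(config$rng_seed, {
    ex <- as.integer(config$exon_lengths)
    intr <- as.integer(config$intron_lengths)
    pad <- as.integer(config$intergenic_bp)
    gene_len <- sum(ex) + sum(intr)
    chrom_len <- gene_len + 2L * pad
    strands <- ifelse(stats::runif(config$n_genes) <
                        config$minus_strand_fraction, "-", "+")
    # exon/intron layout shared by all genes
    bounds <- pad
    exon_iv <- matrix(0L, nrow = length(ex), ncol = 2L)
    intron_iv <- matrix(0L, nrow = length(intr), ncol = 2L)
    cur <- pad
    for (i in seq_along(ex)) {
      exon_iv[i, ] <- c(cur + 1L, cur + ex[i])
      cur <- cur + ex[i]
      if (i <= length(intr)) {
        intron_iv[i, ] <- c(cur + 1L, cur + intr[i])
        cur <- cur + intr[i]
      }
    }
    planted <- list()
    chroms <- character(config$n_genes)
    genes <- vector("list", config$n_genes)
    bg_sites <- list()
    for (gi in seq_len(config$n_genes)) {
      chrom <- random_dna(chrom_len, config$gc_content)
      lo <- exon_iv[1L, 1L]; hi <- exon_iv[nrow(exon_iv), 2L]
      chrom <- scrub_motifs(chrom, lo, hi, strands[gi])
      occupied <- IRanges::IRanges()
      intended <- integer(0)
      # planted clusters for this gene
      pl <- config$planted_clusters
      pl <- if (is.null(pl)) NULL else pl[pl$gene == gi, , drop = FALSE]
      if (!is.null(pl) && nrow(pl) > 0L) {
        for (ri in seq_len(nrow(pl))) {
          ii <- pl$intron[ri]
          stopifnot(ii >= 1L, ii <= nrow(intron_iv))
          center <- as.integer(mean(intron_iv[ii, ]))
          n <- pl$n_sites[ri]
          span <- pl$span_bp[ri]
          first <- center - span %/% 2L
          starts <- if (n == 1L) first else
            first + as.integer(round((seq_len(n) - 1L) * (span - 5L) / (n - 1L)))
          lead <- stats::runif(n) < config$leading_t_fraction
          for (j in seq_len(n))
            chrom <- inject_motif(chrom, starts[j], strands[gi], lead[j])
          occupied <- c(occupied,
                        IRanges::IRanges(min(starts) - 1L, max(starts) + 5L))
          intended <- c(intended, starts)
          planted[[length(planted) + 1L]] <- data.frame(
            gene_id = paste0("gene", gi),
            chrom = paste0("chr", gi), strand = strands[gi],
            start = min(starts), end = max(starts) + 4L,
            n_sites = n, stringsAsFactors = FALSE)
        }
      }
      # spurious background sites
      n_bg <- stats::rpois(1L, config$background_motif_rate * gene_len)
      placed <- 0L; attempts <- 0L
      gsites <- integer(0)
      while (placed < n_bg && attempts < 50L * n_bg) {
        attempts <- attempts + 1L
        g <- as.integer(sample(seq.int(lo + 1L, hi - 6L), 1L))
        fp <- IRanges::IRanges(g - 1L, g + 5L)
        if (length(occupied) > 0L &&
            sum(IRanges::countOverlaps(fp, occupied)) > 0L) next
        chrom <- inject_motif(chrom, g, strands[gi],
                              stats::runif(1) < config$leading_t_fraction)
        occupied <- c(occupied, fp)
        gsites <- c(gsites, g)
        placed <- placed + 1L
      }
      intended <- sort(c(intended, gsites))
      chrom <- enforce_sites(chrom, lo, hi, strands[gi], intended)
      if (length(gsites) > 0L)
        bg_sites[[length(bg_sites) + 1L]] <- data.frame(
          gene_id = paste0("gene", gi), chrom = paste0("chr", gi),
          start = sort(gsites), stringsAsFactors = FALSE)
      chroms[gi] <- chrom
      # annotation: one transcript; CDS from mid first to mid last exon
      exons <- IRanges::IRanges(exon_iv[, 1L], exon_iv[, 2L])
      cds_lo <- exon_iv[1L, 1L] + ex[1L] %/% 2L
      cds_hi <- exon_iv[nrow(exon_iv), 2L] - ex[length(ex)] %/% 2L
      cds <- IRanges::restrict(exons, cds_lo, cds_hi)
      tx <- transcript_model(paste0("tx", gi, ".1"), paste0("gene", gi),
                             paste0("chr", gi), strands[gi], exons, cds)
      genes[[gi]] <- gene_model(paste0("gene", gi), list(tx))
    }
    genome <- Biostrings::DNAStringSet(chroms)
    names(genome) <- paste0("chr", seq_len(config$n_genes))
    names(genes) <- paste0("gene", seq_len(config$n_genes))
    sites <- do.call(rbind, lapply(genes, scan_motifs, genome = genome))
    rownames(sites) <- NULL
    truth <- list(
      planted = if (length(planted)) do.call(rbind, planted) else NULL,
      sites = sites,
      background_sites = if (length(bg_sites))
        do.call(rbind, bg_sites) else NULL)
    list(genome = genome, genes = genes, truth = truth, config = config)
  })
}

#' Simulate CLIP-like peaks over a simulated cohort
#'
#' Exactly round(fraction * n) of the cluster-bearing genes (seeded
#' sample) receive a peak overlapping their first cluster; the
#' remaining cluster genes receive a peak inside the gene that touches
#' no cluster; genes without clusters receive a mid-gene peak. All
#' those peaks pass the log2FE/p filter; \code{n_decoy_peaks} extra
#' peaks are emitted with failing attributes.
#'
#' @param clusters Cluster data.frame (typically from
#'   \code{\link{scan_genome_for_clusters}} on the same simulation).
#' @param genes Gene models of the simulation.
#' @param config \code{\link{simulation_config}}.
#' @return List with peaks (BED-ready data.frame, 1-based closed
#'   coords) and truth (data.frame gene_id, stratum).
#' @export
simulate_peaks <- function(clusters, genes, config) {
  with_seed(config$rng_seed + 1L, {
    w <- as.integer(config$peak_width)
    cluster_genes <- sort(unique(clusters$gene_id))
    n_on <- round(config$peak_on_cluster_fraction * length(cluster_genes))
    on_genes <- if (n_on > 0L)
      sort(sample(cluster_genes, n_on)) else character(0)
    rows <- list()
    truth <- list()
    add_peak <- function(g, start, end, pass) {
      lfe <- if (pass) stats::runif(1, 3, 8) else stats::runif(1, 0.5, 2.9)
      pv <- if (pass) stats::runif(1, 1e-6, 1e-3) else stats::runif(1, 0.002, 0.5)
      data.frame(chrom = g$chrom, start = as.integer(start),
                 end = as.integer(end),
                 name = paste0("peak_", length(rows) + 1L),
                 strand = g$strand, log2_fold_enrichment = lfe,
                 p_value = pv, stringsAsFactors = FALSE)
    }
    for (gid in names(genes)) {
      g <- genes[[gid]]
      span_lo <- IRanges::start(g$span); span_hi <- IRanges::end(g$span)
      gcl <- clusters[clusters$gene_id == gid, , drop = FALSE]
      if (gid %in% on_genes) {
        cs <- gcl$start[1L]
        st <- max(span_lo, cs - w %/% 2L)
        rows[[length(rows) + 1L]] <- add_peak(g, st, st + w - 1L, TRUE)
        truth[[length(truth) + 1L]] <-
          data.frame(gene_id = gid, stratum = "peaks_on_clusters",
                     stringsAsFactors = FALSE)
      } else if (nrow(gcl) > 0L) {
        # a window inside the gene at least 1 bp away from every cluster
        avoid <- IRanges::IRanges(gcl$start - 1L, gcl$end + 1L)
        free <- IRanges::setdiff(g$span, avoid)
        free <- free[IRanges::width(free) >= w]
        if (length(free) == 0L)
          stop("simulate_peaks: no cluster-free window in ", gid)
        st <- IRanges::start(free)[1L] +
          (IRanges::width(free)[1L] - w) %/% 2L
        rows[[length(rows) + 1L]] <- add_peak(g, st, st + w - 1L, TRUE)
        truth[[length(truth) + 1L]] <-
          data.frame(gene_id = gid, stratum = "peaks_off_clusters",
                     stringsAsFactors = FALSE)
      } else {
        st <- (span_lo + span_hi) %/% 2L
        rows[[length(rows) + 1L]] <- add_peak(g, st, st + w - 1L, TRUE)
        truth[[length(truth) + 1L]] <-
          data.frame(gene_id = gid, stratum = "peaks_no_clusters",
                     stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(config$n_decoy_peaks)) {
      g <- genes[[sample(length(genes), 1L)]]
      st <- IRanges::start(g$span) +
        sample.int(IRanges::width(g$span) - w, 1L)
      rows[[length(rows) + 1L]] <- add_peak(g, st, st + w - 1L, FALSE)
    }
    list(peaks = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Write peaks as BED6+2 (log2 fold enrichment, p-value)
#' @param peaks Peaks data.frame (1-based closed coords).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(peaks$chrom, peaks$start - 1L, peaks$end,
                    peaks$name, 0L, peaks$strand,
                    peaks$log2_fold_enrichment,
                    signif(peaks$p_value, 6))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate an isoform differential-expression table over gene strata
#'
#' Per gene, 2-4 isoforms; one differential isoform whose |log2FC| is
#' drawn from the stratum's folded normal (mean, sd) with random sign
#' and a small adjusted p; remaining isoforms get near-zero fold
#' changes and non-significant p.
#'
#' @param strata data.frame gene_id, stratum.
#' @param config \code{\link{simulation_config}}.
#' @param seed_offset Added to the config seed so the expression draw
#'   is independent of the genome draw (default 2).
#' @return data.frame gene_id, isoform_id, log2_fold_change,
#'   p_adjusted.
#' @export
simulate_expression <- function(strata, config, seed_offset = 2L) {
  stopifnot(all(strata$stratum %in% names(config$stratum_effects)))
  with_seed(config$rng_seed + seed_offset, {
    rows <- lapply(seq_len(nrow(strata)), function(i) {
      gid <- strata$gene_id[i]
      eff <- config$stratum_effects[[strata$stratum[i]]]
      n_iso <- if (length(config$isoforms_per_gene) == 1L)
        config$isoforms_per_gene else sample(config$isoforms_per_gene, 1L)
      de_idx <- sample.int(n_iso, 1L)
      lfc <- stats::rnorm(n_iso, 0, 0.2)
      padj <- stats::runif(n_iso, 0.2, 1)
      lfc[de_idx] <- sample(c(-1, 1), 1L) *
        abs(stats::rnorm(1L, eff[["mean"]], eff[["sd"]]))
      padj[de_idx] <- 10^(-stats::runif(1L, 2.5, 8))
      data.frame(gene_id = gid,
                 isoform_id = paste0(gid, ".iso", seq_len(n_iso)),
                 log2_fold_change = lfc, p_adjusted = padj,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' The canonical TrkB-like fixture configuration
#'
#' One gene with three exons separated by two 50 kb introns and
#' mid-intron planted clusters of nine and seven (T)GCATG sites on a
#' clean (motif-free) background — the package's canonical smoke-test
#' geometry.
#'
#' @param rng_seed Seed (default 77).
#' @return \code{\link{simulation_config}}.
#' @export
trkb_fixture_config <- function(rng_seed = 77L) {
  simulation_config(
    rng_seed = rng_seed, n_genes = 1L,
    exon_lengths = c(300L, 150L, 300L),
    intron_lengths = c(50000L, 50000L),
    background_motif_rate = 0,
    minus_strand_fraction = 0,
    planted_clusters = rbind(plant_spec(1L, 1L, 9L, 450L),
                             plant_spec(1L, 2L, 7L, 450L)))
}

#' Write a simulated cohort to disk
#'
#' FASTA, GFF3 and a JSON ground-truth file, all re-readable by the
#' package's own readers.
#'
#' @param sim Result of \code{\link{simulate_genome}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"),
                              width = 70L)
  write_gff3(sim$genes, file.path(dir, "annotation.gff3"))
  truth <- sim$truth
  truth$config <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}
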