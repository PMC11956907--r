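# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately naive: correctness over speed.

# literal seed / extend / merge fixpoint on sorted site start positions
# (5-bp footprints); returns a list of sorted site-index vectors
oracle_call_clusters <- function(starts, window_bp = 500L,
                                 min_sites = 4L, extension_bp = 500L) {
  n <- length(starts)
  if (n == 0L) return(list())
  s <- sort(as.integer(starts))
  e <- s + 4L
  clusters <- list()
  # seeds: every index run of >= min_sites whose footprint span fits
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i + 1L >= min_sites && e[j] - s[i] + 1L <= window_bp)
        clusters[[length(clusters) + 1L]] <- i:j
    }
  }
  if (length(clusters) == 0L) return(list())
  gap_to <- function(idx, k) {
    lo <- min(s[idx]); hi <- max(e[idx])
    if (s[k] > hi) s[k] - hi - 1L
    else if (e[k] < lo) lo - e[k] - 1L
    else 0L
  }
  repeat {
    changed <- FALSE
    # extension: absorb any site strictly closer than extension_bp
    for (ci in seq_along(clusters)) {
      for (k in setdiff(seq_len(n), clusters[[ci]])) {
        if (gap_to(clusters[[ci]], k) < extension_bp) {
          clusters[[ci]] <- sort(c(clusters[[ci]], k))
          changed <- TRUE
        }
      }
    }
    # merge clusters sharing sites or overlapping intervals
    merged <- TRUE
    while (merged && length(clusters) > 1L) {
      merged <- FALSE
      for (a in seq_along(clusters)) {
        for (b in seq_along(clusters)) {
          if (a >= b) next
          ia <- clusters[[a]]; ib <- clusters[[b]]
          overlap <- length(intersect(ia, ib)) > 0L ||
            (min(s[ia]) <= max(e[ib]) && min(s[ib]) <= max(e[ia]))
          if (overlap) {
            clusters[[a]] <- sort(union(ia, ib))
            clusters[[b]] <- NULL
            merged <- TRUE
            changed <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!changed) break
  }
  clusters <- unique(clusters)
  clusters[order(vapply(clusters, function(x) min(s[x]), 0L))]
}

# brute-force overlapping motif count over all offsets
brute_count <- function(seq, motif) {
  k <- nchar(motif)
  L <- nchar(seq)
  if (L < k) return(0L)
  sum(vapply(seq_len(L - k + 1L), function(i)
    substr(seq, i, i + k - 1L) == motif, logical(1)))
}

# independent line-by-line FASTA reader
naive_read_fasta <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur <- sub("\\s.*$", "", sub("^>", "", ln))
      out[[cur]] <- ""
    } else {
      out[[cur]] <- paste0(out[[cur]], ln)
    }
  }
  lapply(out, toupper)
}

# per-base region classification by explicit set membership
oracle_classify <- function(gene, pos, proximal_bp = 500L) {
  base_in <- function(r) {
    length(r) > 0L &&
      any(pos >= IRanges::start(r) & pos <= IRanges::end(r))
  }
  for (tx in gene$transcripts) if (base_in(tx$utr5)) return("utr5")
  for (tx in gene$transcripts) if (base_in(tx$utr3)) return("utr3")
  if (base_in(gene$merged_exons)) return("exon")
  exon_bases <- unlist(lapply(seq_along(gene$merged_exons), function(i)
    seq(IRanges::start(gene$merged_exons)[i],
        IRanges::end(gene$merged_exons)[i])))
  d <- min(abs(pos - exon_bases))
  if (d <= proximal_bp) "proximal_intron" else "distal_intron"
}

# tiny two-gene annotation used by several tests; motif-free background
toy_genome_gene <- function(strand = "+", seq_len_bp = 3000L,
                            seed = 11L) {
  set.seed(seed)
  chrom <- paste0(sample(c("A", "C", "T"), seq_len_bp, replace = TRUE),
                  collapse = "")  # no G -> no GCATG anywhere
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chrT"
  exons <- IRanges::IRanges(c(101L, 1201L, 2501L),
                            c(400L, 1400L, 2800L))
  cds <- IRanges::IRanges(c(251L, 1201L, 2501L),
                          c(400L, 1400L, 2650L))
  tx <- transcript_model("txT.1", "geneT", "chrT", strand, exons, cds)
  list(genome = genome, gene = gene_model("geneT", list(tx)))
}

# plant GCATG occurrences (sense strand) into a gene's genome copy
plant_sites <- function(env, starts, leading_T = TRUE) {
  chrom <- as.character(env$genome[[1L]])
  strand <- env$gene$strand
  for (g in starts) {
    if (strand == "+") {
      substr(chrom, g, g + 4L) <- "GCATG"
      if (leading_T) substr(chrom, g - 1L, g - 1L) <- "T"
    } else {
      substr(chrom, g, g + 4L) <- "CATGC"
      if (leading_T) substr(chrom, g + 5L, g + 5L) <- "A"
    }
  }
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- names(env$genome)
  genome
}
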