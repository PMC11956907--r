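write_peak_fixture <- function(path, rows) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

test_that("peak filter keeps the printed thresholds inclusive", {
  f <- withr::local_tempfile(fileext = ".bed")
  rows <- data.frame(
    chrom = "chr1", start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
    name = paste0("p", 1:4), score = 0, strand = "+",
    lfe = c(3.0, 2.9, 5.0, 4.0), p = c(0.001, 1e-5, 0.0011, 1e-4))
  write_peak_fixture(f, rows)
  pk <- suppressMessages(read_peaks(f))
  # boundary peak (log2FE 3, p 0.001) retained; 2.9 and p 0.0011 dropped
  expect_setequal(pk$name, c("p1", "p4"))
  # BED half-open to 1-based closed conversion
  expect_identical(pk$start[pk$name == "p1"], 1L)
  expect_identical(pk$end[pk$name == "p1"], 50L)
})

test_that("a ten-peak fixture with four passing yields four", {
  set.seed(3)
  f <- withr::local_tempfile(fileext = ".bed")
  lfe <- c(4, 2, 3.5, 1, 3, 2.5, 6, 0.2, 2.99, 8)
  p <- c(1e-4, 1e-4, 0.5, 1e-5, 1e-3, 1e-6, 1e-8, 0.2, 1e-9, 0.0009)
  rows <- data.frame(chrom = "chr1", start = (0:9) * 100,
                     end = (0:9) * 100 + 60, name = paste0("p", 1:10),
                     score = 0, strand = "+", lfe = lfe, p = p)
  write_peak_fixture(f, rows)
  pk <- suppressMessages(read_peaks(f))
  expect_identical(nrow(pk), 4L)  # p1, p5, p7, p10
})

test_that("narrowPeak input converts -log10 p-values", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  rows <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150),
                     name = c("a", "b"), score = 0, strand = "+",
                     signal = c(4, 4), p10 = c(4, 2), q10 = -1, peak = 10)
  write_peak_fixture(f, rows)
  pk <- suppressMessages(read_peaks(f, format = "narrowPeak"))
  expect_identical(pk$name, "a")  # 10^-4 passes, 10^-2 fails
  expect_equal(pk$p_value, 1e-4)
})

toy_cohort <- function() {
  cfg <- simulation_config(
    rng_seed = 5L, n_genes = 4L, background_motif_rate = 0,
    intron_lengths = c(5000L, 5000L), intergenic_bp = 500L,
    planted_clusters = rbind(plant_spec(1L, 1L, 4L, 300L),
                             plant_spec(2L, 1L, 5L, 400L)))
  sim <- simulate_genome(cfg)
  res <- scan_genome_for_clusters(sim$genes, sim$genome, classify = FALSE)
  list(sim = sim, clusters = res$clusters)
}

test_that("peaks are assigned to overlapping genes, strand-matched", {
  tc <- toy_cohort()
  genes <- tc$sim$genes
  g1 <- genes$gene1
  mid <- as.integer(mean(c(IRanges::start(g1$span), IRanges::end(g1$span))))
  peaks <- data.frame(chrom = "chr1", start = mid, end = mid + 99L,
                      name = "pk", strand = g1$strand,
                      log2_fold_enrichment = 5, p_value = 1e-4,
                      stringsAsFactors = FALSE)
  asg <- assign_peaks_to_genes(peaks, genes)
  expect_identical(asg$gene_id, "gene1")
  # wrong strand: dropped unless strand_matched = FALSE
  peaks$strand <- if (g1$strand == "+") "-" else "+"
  expect_identical(nrow(assign_peaks_to_genes(peaks, genes)), 0L)
  expect_identical(
    assign_peaks_to_genes(peaks, genes, strand_matched = FALSE)$gene_id,
    "gene1")
  # intergenic peak: unassigned
  peaks2 <- peaks
  peaks2$start <- 1L; peaks2$end <- 50L
  expect_identical(nrow(assign_peaks_to_genes(peaks2, genes)), 0L)
})

test_that("peak-gene assignment agrees with an all-pairs oracle", {
  tc <- toy_cohort()
  genes <- tc$sim$genes
  set.seed(44)
  n <- 80L
  chroms <- paste0("chr", sample(4, n, replace = TRUE))
  starts <- sample.int(11000L, n)
  peaks <- data.frame(chrom = chroms, start = starts,
                      end = starts + sample(20:200, n, replace = TRUE),
                      name = paste0("p", seq_len(n)),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      log2_fold_enrichment = 5, p_value = 1e-4,
                      stringsAsFactors = FALSE)
  asg <- assign_peaks_to_genes(peaks, genes)
  want <- do.call(rbind, lapply(seq_len(n), function(i) {
    hits <- Filter(function(g)
      g$chrom == peaks$chrom[i] && g$strand == peaks$strand[i] &&
        peaks$start[i] <= IRanges::end(g$span) &&
        peaks$end[i] >= IRanges::start(g$span), genes)
    if (length(hits) == 0L) return(NULL)
    data.frame(name = peaks$name[i],
               gene_id = vapply(hits, `[[`, "", "gene_id"))
  }))
  got <- asg[order(asg$name, asg$gene_id), c("name", "gene_id")]
  want <- want[order(want$name, want$gene_id), ]
  expect_identical(unname(as.list(got)), unname(as.list(want)))
})

test_that("Venn counts are disjoint set arithmetic", {
  expect_identical(overlap_gene_sets(c("a", "b"), "c"),
                   list(only_clusters = 2L, only_peaks = 1L, both = 0L))
  expect_identical(overlap_gene_sets(c("a", "b"), c("b", "a")),
                   list(only_clusters = 0L, only_peaks = 0L, both = 2L))
  set.seed(10)
  univ <- paste0("g", 1:1000)
  inter <- sample(univ, 37)
  a <- c(inter, sample(setdiff(univ, inter), 163))
  b <- c(inter, sample(setdiff(univ, c(a, inter)), 113))
  v <- overlap_gene_sets(a, b)
  expect_identical(v$both, 37L)
  expect_identical(v$only_clusters, 163L)
  expect_identical(v$only_peaks, 113L)
})

test_that("gene strata partition the peak-bearing genes", {
  tc <- toy_cohort()
  cl <- tc$clusters
  # peaks: on gene1's cluster, inside gene2 but off-cluster, in gene3
  g2 <- tc$sim$genes$gene2
  peaks <- data.frame(
    chrom = c("chr1", "chr2", "chr3"),
    start = c(cl$start[cl$gene_id == "gene1"][1],
              IRanges::start(g2$span), 2000L),
    name = paste0("p", 1:3),
    strand = vapply(tc$sim$genes[1:3], `[[`, "", "strand"),
    log2_fold_enrichment = 5, p_value = 1e-4,
    stringsAsFactors = FALSE)
  peaks$end <- peaks$start + 49L
  asg <- assign_peaks_to_genes(peaks, tc$sim$genes)
  st <- stratify_peaks_on_clusters(asg, cl)
  expect_identical(st$genes_peaks_on_clusters, "gene1")
  expect_identical(st$genes_peaks_off_clusters, "gene2")
  expect_identical(st$genes_peaks_no_clusters, "gene3")
  # partition property
  expect_setequal(c(st$genes_peaks_on_clusters,
                    st$genes_peaks_off_clusters,
                    st$genes_peaks_no_clusters), st$genes_with_peaks)
  tab <- strata_table(st)
  expect_identical(nrow(tab), length(st$genes_with_peaks))
  # exactly coincident peak-cluster interval counts as on-cluster
  pk1 <- data.frame(chrom = cl$chrom[1], start = cl$start[1],
                    end = cl$end[1], name = "x", strand = cl$strand[1],
                    log2_fold_enrichment = 5, p_value = 1e-4,
                    gene_id = cl$gene_id[1], stringsAsFactors = FALSE)
  st2 <- stratify_peaks_on_clusters(pk1, cl)
  expect_identical(st2$genes_peaks_on_clusters, cl$gene_id[1])
})

test_that("planted on-cluster fraction is recovered exactly", {
  cfg <- simulation_config(
    rng_seed = 17L, n_genes = 8L, background_motif_rate = 0,
    intron_lengths = c(4000L, 4000L), intergenic_bp = 500L,
    peak_on_cluster_fraction = 0.25,
    planted_clusters = do.call(rbind, lapply(1:4, function(i)
      plant_spec(i, 1L + i %% 2L, 4L + i %% 3L, 400L))))
  sim <- simulate_genome(cfg)
  res <- scan_genome_for_clusters(sim$genes, sim$genome, classify = FALSE)
  pk <- simulate_peaks(res$clusters, sim$genes, cfg)
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk$peaks, f)
  peaks <- suppressMessages(read_peaks(f))
  asg <- assign_peaks_to_genes(peaks, sim$genes)
  st <- stratify_peaks_on_clusters(asg, res$clusters)
  truth_on <- pk$truth$gene_id[pk$truth$stratum == "peaks_on_clusters"]
  expect_identical(length(truth_on), 1L)  # round(0.25 * 4)
  expect_setequal(st$genes_peaks_on_clusters, truth_on)
  expect_setequal(
    st$genes_peaks_off_clusters,
    pk$truth$gene_id[pk$truth$stratum == "peaks_off_clusters"])
  expect_setequal(
    st$genes_peaks_no_clusters,
    pk$truth$gene_id[pk$truth$stratum == "peaks_no_clusters"])
})
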