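test_that("read_genome loads, normalizes case and maps non-ACGTN to N", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 descriptive text", "ACGT",
               ">chr2", "acgtn", ">chr3", "ACRYGT"), fa)
  g <- read_genome(fa)
  expect_identical(names(g), c("chr1", "chr2", "chr3"))
  expect_identical(as.character(g[["chr1"]]), "ACGT")
  expect_identical(as.character(g[["chr2"]]), "ACGTN")
  expect_identical(as.character(g[["chr3"]]), "ACNNGT")
})

test_that("read_genome matches an independent line-by-line parser", {
  set.seed(5)
  fa <- withr::local_tempfile(fileext = ".fa")
  recs <- vapply(1:3, function(i)
    paste0(sample(c("A", "C", "G", "T"), 40 + 13 * i, replace = TRUE),
           collapse = ""), character(1))
  writeLines(unlist(lapply(1:3, function(i)
    c(paste0(">ctg", i), substring(recs[i], 1, 25),
      substring(recs[i], 26)))), fa)
  g <- read_genome(fa)
  ref <- naive_read_fasta(fa)
  expect_identical(length(g), 3L)
  for (nm in names(ref))
    expect_identical(as.character(g[[nm]]), ref[[nm]])
})

test_that("read_genome rejects missing files and duplicate names", {
  expect_error(read_genome(file.path(tempdir(), "nope.fa")), "no such")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(read_genome(fa), "duplicate")
})

test_that("genome_subseq is strand-correct and bounds-checked", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACGTTGCAT"))
  expect_identical(genome_subseq(g, "chr1", 3, 6, "+"), "CGTT")
  expect_identical(genome_subseq(g, "chr1", 3, 6, "-"), "AACG")
  expect_error(genome_subseq(g, "chr1", 0, 4), "outside")
  expect_error(genome_subseq(g, "chr2", 1, 2), "unknown")
})

test_that("UTR inference splits exons-minus-CDS at the CDS by strand", {
  # '+' strand: exons [1,100],[201,300]; cds [51,100],[201,250]
  exons <- IRanges::IRanges(c(1L, 201L), c(100L, 300L))
  cds <- IRanges::IRanges(c(51L, 201L), c(100L, 250L))
  tx <- transcript_model("t1", "g1", "c", "+", exons, cds)
  expect_identical(as.data.frame(tx$utr5)[, 1:2],
                   data.frame(start = 1L, end = 50L))
  expect_identical(as.data.frame(tx$utr3)[, 1:2],
                   data.frame(start = 251L, end = 300L))
  # mirrored on '-'
  txm <- transcript_model("t2", "g1", "c", "-", exons, cds)
  expect_identical(IRanges::start(txm$utr5), 251L)
  expect_identical(IRanges::start(txm$utr3), 1L)
  # exons == cds: no UTR; empty cds: no UTR labels
  tx3 <- transcript_model("t3", "g1", "c", "+", exons, exons)
  expect_length(tx3$utr5, 0)
  expect_length(tx3$utr3, 0)
  tx4 <- transcript_model("t4", "g1", "c", "+", exons)
  expect_length(tx4$utr5, 0)
  expect_error(
    transcript_model("t5", "g1", "c", "+", exons,
                     IRanges::IRanges(120L, 180L)),
    "not contained")
})

test_that("per-base accounting: |exons| = |cds| + |utr5| + |utr3|", {
  set.seed(42)
  for (rep in 1:25) {
    n_ex <- sample(1:4, 1)
    starts <- cumsum(sample(50:500, n_ex)) + (0:(n_ex - 1)) * 300
    widths <- sample(30:200, n_ex, replace = TRUE)
    exons <- IRanges::IRanges(starts, width = widths)
    # random CDS: a sub-slice of the exon body
    total <- sum(widths)
    a <- sort(sample(total, 2))
    base_of <- unlist(lapply(seq_len(n_ex), function(i)
      seq(IRanges::start(exons)[i], IRanges::end(exons)[i])))
    cds_bases <- base_of[a[1]:a[2]]
    cds <- IRanges::reduce(IRanges::IRanges(cds_bases, cds_bases))
    strand <- sample(c("+", "-"), 1)
    tx <- transcript_model("t", "g", "c", strand, exons, cds)
    expect_identical(
      sum(IRanges::width(tx$exons)),
      sum(IRanges::width(tx$cds)) + sum(IRanges::width(tx$utr5)) +
        sum(IRanges::width(tx$utr3)))
    # brute-force per-base split agrees
    lo <- min(cds_bases); hi <- max(cds_bases)
    left <- setdiff(base_of[base_of < lo], cds_bases)
    right <- setdiff(base_of[base_of > hi], cds_bases)
    u5 <- if (strand == "+") left else right
    expect_setequal(
      unlist(lapply(seq_along(tx$utr5), function(i)
        seq(IRanges::start(tx$utr5)[i], IRanges::end(tx$utr5)[i]))),
      u5)
  }
})

test_that("introns are the exon gaps and tile the span with exons", {
  exons <- IRanges::IRanges(c(1L, 201L), c(100L, 300L))
  tx <- transcript_model("t", "g", "c", "+", exons)
  g <- gene_model("g", list(tx))
  expect_identical(IRanges::start(g$introns), 101L)
  expect_identical(IRanges::end(g$introns), 200L)
  # single-exon gene: none
  tx1 <- transcript_model("t1", "g1", "c", "+",
                          IRanges::IRanges(10L, 99L))
  expect_length(gene_model("g1", list(tx1))$introns, 0)
  # TrkB-like geometry: 3 exons, 50 kb and 15 kb gaps
  ex3 <- IRanges::IRanges(c(1L, 50101L, 65301L),
                          c(100L, 50300L, 65500L))
  g3 <- gene_model("g3", list(transcript_model("t3", "g3", "c", "+", ex3)))
  expect_identical(IRanges::width(g3$introns), c(50000L, 15000L))
  # partition property
  both <- IRanges::reduce(c(g3$introns, g3$merged_exons))
  expect_identical(as.data.frame(both)[, 1:2],
                   as.data.frame(g3$span)[, 1:2])
  expect_length(IRanges::intersect(g3$introns, g3$merged_exons), 0)
})

make_toy_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t11\t500\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t11\t500\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t11\t100\t.\t+\t.\tParent=gA.t1",
    "chr1\tsrc\texon\t201\t500\t.\t+\t.\tParent=gA.t1",
    "chr1\tsrc\tCDS\t51\t100\t.\t+\t0\tParent=gA.t1",
    "chr1\tsrc\tCDS\t201\t400\t.\t+\t0\tParent=gA.t1",
    "chr1\tsrc\tmRNA\t11\t300\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\tsrc\texon\t11\t300\t.\t+\t.\tParent=gA.t2",
    "chr2\tsrc\tgene\t1001\t2000\t.\t-\t.\tID=gB",
    "chr2\tsrc\tmRNA\t1001\t2000\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr2\tsrc\texon\t1001\t1200\t.\t-\t.\tParent=gB.t1",
    "chr2\tsrc\texon\t1801\t2000\t.\t-\t.\tParent=gB.t1",
    "chr2\tsrc\tCDS\t1101\t1200\t.\t-\t0\tParent=gB.t1",
    "chr2\tsrc\tCDS\t1801\t1900\t.\t-\t0\tParent=gB.t1"), path)
}

make_toy_gtf <- function(path) {
  at <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  writeLines(c(
    paste0("chr1\tsrc\texon\t11\t100\t.\t+\t.\t", at("gA", "gA.t1")),
    paste0("chr1\tsrc\texon\t201\t500\t.\t+\t.\t", at("gA", "gA.t1")),
    paste0("chr1\tsrc\tCDS\t51\t100\t.\t+\t0\t", at("gA", "gA.t1")),
    paste0("chr1\tsrc\tCDS\t201\t400\t.\t+\t0\t", at("gA", "gA.t1")),
    paste0("chr1\tsrc\texon\t11\t300\t.\t+\t.\t", at("gA", "gA.t2")),
    paste0("chr2\tsrc\texon\t1001\t1200\t.\t-\t.\t", at("gB", "gB.t1")),
    paste0("chr2\tsrc\texon\t1801\t2000\t.\t-\t.\t", at("gB", "gB.t1")),
    paste0("chr2\tsrc\tCDS\t1101\t1200\t.\t-\t0\t", at("gB", "gB.t1")),
    paste0("chr2\tsrc\tCDS\t1801\t1900\t.\t-\t0\t", at("gB", "gB.t1"))),
    path)
}

test_that("GFF3 and GTF dialects of one toy annotation agree", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  make_toy_gff3(gff)
  make_toy_gtf(gtf)
  a <- read_annotation(gff, "gff3")
  b <- read_annotation(gtf, "gtf")
  expect_named(a, c("gA", "gB"))
  expect_length(a$gA$transcripts, 2)
  expect_length(a$gB$transcripts, 1)
  for (gid in names(a)) {
    expect_identical(as.data.frame(a[[gid]]$merged_exons),
                     as.data.frame(b[[gid]]$merged_exons))
    expect_identical(a[[gid]]$strand, b[[gid]]$strand)
    ta <- a[[gid]]$transcripts[[1]]
    tb <- b[[gid]]$transcripts[[1]]
    expect_identical(as.data.frame(ta$cds), as.data.frame(tb$cds))
    expect_identical(as.data.frame(ta$utr5), as.data.frame(tb$utr5))
  }
  # coordinate convention: file start=11 end=100 -> width 90 interval
  expect_identical(IRanges::start(a$gA$transcripts[[1]]$exons)[1], 11L)
  expect_identical(IRanges::width(a$gA$transcripts[[1]]$exons)[1], 90L)
})

test_that("GFF3 writer round-trips gene models", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  make_toy_gff3(gff)
  genes <- read_annotation(gff, "gff3")
  out <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, out)
  back <- read_annotation(out, "gff3")
  expect_identical(names(back), names(genes))
  for (gid in names(genes)) {
    expect_identical(as.data.frame(back[[gid]]$merged_exons),
                     as.data.frame(genes[[gid]]$merged_exons))
    for (k in seq_along(genes[[gid]]$transcripts)) {
      ta <- genes[[gid]]$transcripts[[k]]
      ids <- vapply(back[[gid]]$transcripts, `[[`, "", "transcript_id")
      tb <- back[[gid]]$transcripts[[which(ids == ta$transcript_id)]]
      for (f in c("exons", "cds", "utr5", "utr3"))
        expect_identical(as.data.frame(tb[[f]]), as.data.frame(ta[[f]]))
    }
  }
})
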