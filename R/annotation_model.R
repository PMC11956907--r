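#' Read a genome FASTA into a normalized DNAStringSet
#'
#' Loads every record, keeps the first whitespace-delimited token of each
#' header as the chromosome name, uppercases the sequence and maps any
#' character outside ACGTN to N.
#'
#' @param path Path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet} named by chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("read_genome: no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("read_genome: no FASTA records in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("read_genome: duplicate chromosome name: ",
         names(seqs)[duplicated(names(seqs))][1L])
  if (any(Biostrings::width(seqs) == 0L))
    stop("read_genome: empty sequence record")
  # normalize: uppercase, anything outside ACGTN -> N
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGTN]", "N", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  out
}

#' Extract a strand-correct subsequence from a genome
#'
#' @param genome DNAStringSet from \code{\link{read_genome}}.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed genomic coordinates.
#' @param strand "+" or "-"; "-" returns the reverse complement.
#' @return A character scalar.
#' @export
genome_subseq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("genome_subseq: unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 1L || end > len || start > end)
    stop("genome_subseq: interval [", start, ",", end,
         "] outside chromosome ", chrom, " (length ", len, ")")
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

norm_iranges <- function(x) {
  IRanges::reduce(x)  # reduce returns sorted, disjoint ranges
}

#' Construct a transcript model
#'
#' Coordinates are 1-based closed \link[IRanges]{IRanges} throughout the
#' package; file formats are converted at the boundary. UTR intervals are
#' inferred from exons and CDS via \code{\link{infer_utr_exons}}.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons IRanges of exon intervals.
#' @param cds IRanges of CDS intervals (may be empty for non-coding
#'   transcripts, which then carry no UTR labels).
#' @return A list of class \code{transcript_model} with fields
#'   \code{utr5} and \code{utr3} filled in.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds = IRanges::IRanges()) {
  stopifnot(strand %in% c("+", "-"))
  exons <- norm_iranges(exons)
  cds <- norm_iranges(cds)
  if (length(exons) == 0L)
    stop("transcript_model: transcript ", transcript_id, " has no exons")
  if (length(cds) > 0L &&
      sum(IRanges::width(IRanges::intersect(cds, exons))) !=
      sum(IRanges::width(cds)))
    stop("transcript_model: CDS of ", transcript_id,
         " not contained in its exons")
  tx <- structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exons = exons,
    cds = cds,
    utr5 = IRanges::IRanges(),
    utr3 = IRanges::IRanges()
  ), class = "transcript_model")
  infer_utr_exons(tx)
}

#' Infer UTR intervals of a transcript from its exons and CDS
#'
#' The per-base set difference exons minus CDS is split at the CDS span:
#' on "+" transcripts, bases 5' (lower coordinate) of the first CDS base
#' are 5'UTR and bases 3' of the last CDS base are 3'UTR; mirrored on
#' "-". Non-coding transcripts (empty CDS) get empty UTRs.
#'
#' @param tx A \code{\link{transcript_model}}.
#' @return The transcript with \code{utr5}/\code{utr3} set.
#' @export
infer_utr_exons <- function(tx) {
  stopifnot(inherits(tx, "transcript_model"))
  if (length(tx$cds) == 0L) {
    tx$utr5 <- IRanges::IRanges()
    tx$utr3 <- IRanges::IRanges()
    return(tx)
  }
  utr <- IRanges::setdiff(tx$exons, tx$cds)
  cds_lo <- min(IRanges::start(tx$cds))
  cds_hi <- max(IRanges::end(tx$cds))
  left <- utr[IRanges::end(utr) < cds_lo]
  right <- utr[IRanges::start(utr) > cds_hi]
  if (sum(IRanges::width(left)) + sum(IRanges::width(right)) !=
      sum(IRanges::width(utr)))
    stop("infer_utr_exons: CDS of ", tx$transcript_id,
         " does not tile its exon span (internal exonic gap in CDS)")
  if (tx$strand == "+") {
    tx$utr5 <- left; tx$utr3 <- right
  } else {
    tx$utr5 <- right; tx$utr3 <- left
  }
  tx
}

#' Construct a gene model from its transcripts
#'
#' The gene-level interval view is the union of all transcript exons
#' (merged_exons); introns are the gaps between consecutive merged exons
#' within the gene span, so a base is intronic only when no transcript
#' has an exon there.
#'
#' @param gene_id Identifier.
#' @param transcripts List of \code{\link{transcript_model}} objects, all
#'   on one chromosome and strand.
#' @return A list of class \code{gene_model}.
#' @export
gene_model <- function(gene_id, transcripts) {
  if (length(transcripts) == 0L)
    stop("gene_model: gene ", gene_id, " has no transcripts")
  chrom <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("gene_model: transcripts of ", gene_id,
         " span multiple chromosomes or strands")
  merged <- norm_iranges(do.call(c, lapply(transcripts, `[[`, "exons")))
  span <- IRanges::IRanges(min(IRanges::start(merged)),
                           max(IRanges::end(merged)))
  g <- structure(list(
    gene_id = as.character(gene_id),
    chrom = chrom,
    strand = strand,
    span = span,
    transcripts = transcripts,
    merged_exons = merged,
    introns = IRanges::IRanges()
  ), class = "gene_model")
  g$introns <- derive_introns(g)
  g
}

#' Derive intron intervals of a gene
#'
#' Introns are the gaps between consecutive merged exons within the gene
#' span; a single-exon gene has none.
#'
#' @param gene A \code{\link{gene_model}}.
#' @return An IRanges of intron intervals, sorted and disjoint.
#' @export
derive_introns <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  IRanges::setdiff(gene$span, gene$merged_exons)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d transcript(s), %d exon(s), %d intron(s)\n",
              x$gene_id, x$chrom, IRanges::start(x$span),
              IRanges::end(x$span), x$strand,
              length(x$transcripts), length(x$merged_exons),
              length(x$introns)))
  invisible(x)
}

# group ranges of one feature type by the transcript id they belong to
split_by_tx <- function(gr, tx_of) {
  sp <- split(seq_along(gr), tx_of)
  lapply(sp, function(i) IRanges::ranges(gr[i]))
}

#' Read a gene annotation (GFF3 or GTF) into gene models
#'
#' Requires gene/mRNA(or transcript)/exon/CDS records with parent links
#' (GFF3 ID/Parent attributes, or GTF gene_id/transcript_id). UTR records
#' in the file are ignored: UTRs are always re-inferred from exons and
#' CDS so annotations lacking UTR lines are handled uniformly.
#'
#' @param path Path to the annotation file.
#' @param dialect "gff3" or "gtf".
#' @return A named list of \code{\link{gene_model}} objects.
#' @export
read_annotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_annotation: no such file: ", path)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  type <- as.character(gr$type)
  is_exon <- type == "exon"
  is_cds <- type == "CDS"
  if (!any(is_exon)) stop("read_annotation: no exon records in ", path)

  if (dialect == "gff3") {
    par <- gr$Parent
    first_parent <- function(i) {
      p <- par[[i]]
      if (length(p) == 0L) NA_character_ else as.character(p)
    }
    tx_rows <- which(type %in% c("mRNA", "transcript"))
    tx_ids <- as.character(gr$ID[tx_rows])
    tx_gene <- vapply(tx_rows, first_parent, character(1))
    feat_parents <- function(rows) {
      lapply(rows, function(i) as.character(par[[i]]))
    }
    exon_par <- feat_parents(which(is_exon))
    cds_par <- feat_parents(which(is_cds))
  } else {
    tx_all <- as.character(gr$transcript_id)
    gene_all <- as.character(gr$gene_id)
    keep <- is_exon | is_cds
    ids <- unique(data.frame(tx = tx_all[keep], gene = gene_all[keep],
                             stringsAsFactors = FALSE))
    tx_ids <- ids$tx
    tx_gene <- ids$gene
    exon_par <- as.list(tx_all[is_exon])
    cds_par <- as.list(tx_all[is_cds])
  }
  if (anyNA(tx_gene))
    stop("read_annotation: transcript without a parent gene")
  names(tx_gene) <- tx_ids

  expand <- function(rows, parents) {
    n <- lengths(parents)
    data.frame(row = rep(rows, n), tx = unlist(parents),
               stringsAsFactors = FALSE)
  }
  exon_map <- expand(which(is_exon), exon_par)
  cds_map <- expand(which(is_cds), cds_par)
  if (any(!exon_map$tx %in% tx_ids))
    stop("read_annotation: exon with unknown parent transcript: ",
         setdiff(exon_map$tx, tx_ids)[1L])
  if (any(!cds_map$tx %in% tx_ids))
    stop("read_annotation: CDS with unknown parent transcript: ",
         setdiff(cds_map$tx, tx_ids)[1L])

  rng <- IRanges::ranges(gr)
  chrom_all <- as.character(GenomicRanges::seqnames(gr))
  strand_all <- as.character(GenomicRanges::strand(gr))

  txs <- lapply(tx_ids, function(tid) {
    er <- exon_map$row[exon_map$tx == tid]
    cr <- cds_map$row[cds_map$tx == tid]
    if (length(er) == 0L)
      stop("read_annotation: transcript ", tid, " has no exons")
    transcript_model(
      transcript_id = tid,
      gene_id = tx_gene[[tid]],
      chrom = chrom_all[er[1L]],
      strand = strand_all[er[1L]],
      exons = rng[er],
      cds = rng[cr]
    )
  })
  names(txs) <- tx_ids

  genes <- lapply(split(txs, tx_gene[tx_ids]), function(tt) {
    gene_model(tt[[1L]]$gene_id, unname(tt))
  })
  genes[order(names(genes))]
}

#' Write gene models (with inferred UTRs) to GFF3
#'
#' Emits gene, mRNA, exon, CDS and five_prime_UTR/three_prime_UTR
#' records with ID/Parent links, re-readable by
#' \code{\link{read_annotation}}.
#'
#' @param genes List of \code{\link{gene_model}} objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, r, strand, attrs) {
    sprintf("%s\trbclust\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, IRanges::start(r), IRanges::end(r), strand, attrs)
  }
  for (g in genes) {
    lines <- c(lines, fmt(g$chrom, "gene", g$span, g$strand,
                          sprintf("ID=%s", g$gene_id)))
    for (tx in g$transcripts) {
      tspan <- IRanges::IRanges(min(IRanges::start(tx$exons)),
                                max(IRanges::end(tx$exons)))
      lines <- c(lines, fmt(g$chrom, "mRNA", tspan, g$strand,
                            sprintf("ID=%s;Parent=%s",
                                    tx$transcript_id, g$gene_id)))
      emit <- function(type, rr) {
        if (length(rr) == 0L) return(character(0))
        vapply(seq_along(rr), function(i)
          fmt(g$chrom, type, rr[i], g$strand,
              sprintf("Parent=%s", tx$transcript_id)), character(1))
      }
      lines <- c(lines, emit("exon", tx$exons), emit("CDS", tx$cds),
                 emit("five_prime_UTR", tx$utr5),
                 emit("three_prime_UTR", tx$utr3))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
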