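#' Read an isoform differential-expression table
#'
#' Tab-separated with columns gene_id, isoform_id, log2_fold_change,
#' p_adjusted (header required). An is_differential flag is added at
#' the supplied adjusted-p cutoff.
#'
#' @param path TSV path.
#' @param de_alpha Adjusted-p cutoff marking an isoform differential
#'   (default 0.05); upstream DE calling is consumed as-is.
#' @return data.frame of isoform records.
#' @export
read_isoform_table <- function(path, de_alpha = 0.05) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "isoform_id", "log2_fold_change", "p_adjusted")
  if (!all(need %in% names(tab)))
    stop("read_isoform_table: missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (any(tab$p_adjusted < 0 | tab$p_adjusted > 1))
    stop("read_isoform_table: p_adjusted outside [0, 1]")
  tab$is_differential <- tab$p_adjusted <= de_alpha
  tab
}

# % fold change of an unsigned log2 fold change: 2-fold == 100%
percent_fold_change <- function(log2fc) (2^abs(log2fc) - 1) * 100

# per-gene isoform-modulation summary over differential isoforms;
# genes without a differential isoform get NA
gene_stat <- function(records, summary = c("max", "mean")) {
  summary <- match.arg(summary)
  de <- records[records$is_differential, , drop = FALSE]
  if (nrow(de) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  f <- if (summary == "max") max else mean
  tapply(abs(de$log2_fold_change), de$gene_id, f)
}

#' Percent-changed curve and fold-change summary per gene stratum
#'
#' For each stratum and each percent-fold-change threshold t, the
#' percent of stratum genes having at least one differential isoform
#' with (2^|log2FC| - 1) * 100 >= t; plus the stratum mean and SEM of
#' the per-gene summary statistic (max |log2FC| over differential
#' isoforms by default) among genes with a differential isoform.
#' Genes absent from the expression table are reported via message()
#' and excluded.
#'
#' @param records Isoform records (\code{\link{read_isoform_table}}).
#' @param strata data.frame with gene_id, stratum columns
#'   (\code{\link{strata_table}}).
#' @param thresholds Percent thresholds (default seq(5, 100, 5)).
#' @param summary Per-gene statistic, "max" (default) or "mean".
#' @return List with \code{curves} (data.frame stratum, threshold,
#'   percent, n_changed, n_genes) and \code{summaries} (data.frame
#'   stratum, n_genes, n_genes_differential, mean_abs_log2fc, sem).
#' @export
percent_change_curve <- function(records, strata,
                                 thresholds = seq(5, 100, by = 5),
                                 summary = "max") {
  missing <- setdiff(strata$gene_id, records$gene_id)
  if (length(missing) > 0L) {
    message("percent_change_curve: ", length(missing),
            " stratum gene(s) missing from the expression table; excluded")
    strata <- strata[!strata$gene_id %in% missing, , drop = FALSE]
  }
  if (nrow(strata) == 0L) stop("percent_change_curve: no genes left")
  de <- records[records$is_differential, , drop = FALSE]
  # per gene, the largest percent fold change among differential isoforms
  max_pct <- tapply(percent_fold_change(de$log2_fold_change),
                    de$gene_id, max)
  stat <- gene_stat(records, summary)
  strata_names <- unique(strata$stratum)
  curves <- do.call(rbind, lapply(strata_names, function(st) {
    gids <- strata$gene_id[strata$stratum == st]
    gp <- max_pct[intersect(gids, names(max_pct))]
    data.frame(stratum = st, threshold = thresholds,
               percent = vapply(thresholds, function(t)
                 100 * sum(gp >= t) / length(gids), numeric(1)),
               n_changed = vapply(thresholds, function(t)
                 sum(gp >= t), numeric(1)),
               n_genes = length(gids), stringsAsFactors = FALSE)
  }))
  summaries <- do.call(rbind, lapply(strata_names, function(st) {
    gids <- strata$gene_id[strata$stratum == st]
    v <- stat[intersect(gids, names(stat))]
    data.frame(stratum = st, n_genes = length(gids),
               n_genes_differential = length(v),
               mean_abs_log2fc = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1L)
                 stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(curves = curves, summaries = summaries)
}

#' Pairwise stratum comparisons of isoform modulation
#'
#' For every stratum pair: a chi-square test on changed/unchanged gene
#' counts at each percent-fold-change threshold, and a two-sided
#' Student's t test on the per-gene summary statistic (among genes with
#' a differential isoform). Significance is declared below
#' \code{params$significance_p} (default 0.01).
#'
#' @param records Isoform records.
#' @param strata data.frame gene_id, stratum.
#' @param params \code{\link{analysis_params}}.
#' @param thresholds Percent thresholds for the chi-square series.
#' @param summary Per-gene statistic, "max" or "mean".
#' @return List with \code{chisq} (data.frame stratum_a, stratum_b,
#'   threshold, p_value, significant) and \code{t_test} (data.frame
#'   stratum_a, stratum_b, mean_a, sem_a, mean_b, sem_b, t, p_value,
#'   significant).
#' @export
compare_strata <- function(records, strata, params = analysis_params(),
                           thresholds = seq(5, 100, by = 5),
                           summary = "max") {
  strata_names <- unique(strata$stratum)
  if (length(strata_names) < 2L)
    stop("compare_strata: need at least 2 non-empty strata")
  pc <- percent_change_curve(records, strata, thresholds, summary)
  stat <- gene_stat(records, summary)
  per_stratum_stat <- lapply(strata_names, function(st) {
    gids <- strata$gene_id[strata$stratum == st]
    unname(stat[intersect(gids, names(stat))])
  })
  names(per_stratum_stat) <- strata_names
  bad <- strata_names[vapply(per_stratum_stat, length, 0L) < 2L]
  if (length(bad) > 0L)
    stop("compare_strata: stratum '", bad[1L],
         "' has fewer than 2 genes with differential isoforms; ",
         "tests are undefined")
  pairs <- utils::combn(strata_names, 2L, simplify = FALSE)
  chisq <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(thresholds, function(t) {
      rows <- pc$curves[pc$curves$threshold == t &
                          pc$curves$stratum %in% pr, ]
      tab <- cbind(changed = rows$n_changed,
                   unchanged = rows$n_genes - rows$n_changed)
      p <- if (any(colSums(tab) == 0)) 1 else suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value)
      data.frame(stratum_a = pr[1L], stratum_b = pr[2L], threshold = t,
                 p_value = p, significant = p < params$significance_p,
                 stringsAsFactors = FALSE)
    }))
  }))
  t_test <- do.call(rbind, lapply(pairs, function(pr) {
    a <- per_stratum_stat[[pr[1L]]]
    b <- per_stratum_stat[[pr[2L]]]
    tt <- stats::t.test(a, b, alternative = "two.sided")
    data.frame(stratum_a = pr[1L], stratum_b = pr[2L],
               mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
               mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)),
               t = unname(tt$statistic), p_value = tt$p.value,
               significant = tt$p.value < params$significance_p,
               stringsAsFactors = FALSE)
  }))
  list(chisq = chisq, t_test = t_test, curves = pc$curves,
       summaries = pc$summaries)
}
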