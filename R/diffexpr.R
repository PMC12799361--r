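# Paired tumor-versus-normal differential expression on pseudobulk counts.

#' Paired differential expression test on pseudobulk samples
#'
#' Default engine (`"ttest"`): per patient, the gene-wise log2 ratio of
#' tumor to normal CPM (counts per million, pseudocount `pseudocount` added
#' to both) is computed; the reported log2 fold-change is the mean ratio
#' across patients and the p-value a two-sided paired t-test on those
#' per-patient ratios (one-sample t against zero). Genes with zero counts in
#' every sample get `log2fc = 0`, `p = 1`. Degenerate genes whose per-patient
#' ratios are all identical get `p = 1` when the common ratio is zero and
#' `p = 0` otherwise.
#'
#' The optional `"deseq2"` engine fits the paired Wald model
#' `~ patient + tissue` with DESeq2 (if installed) and returns its
#' shrinkage-free log2 fold-changes and raw p-values through the same
#' interface.
#'
#' @param pb pseudobulk [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#'   from [makePseudobulk()].
#' @param min_patients minimum number of patients with both tissues
#'   (default 3).
#' @param pseudocount added to CPM before the log ratio (default 0.5).
#' @param engine `"ttest"` (default) or `"deseq2"`.
#' @return A DEG table: data.frame with `gene_id`, `log2fc` (tumor minus
#'   normal), `p_value`, `direction` (`"up"` iff `log2fc > 0`), and `is_deg`
#'   (all `NA` until [filterDEGs()] is applied).
#' @export
pairedDE <- function(pb, min_patients = 3, pseudocount = 0.5,
                     engine = c("ttest", "deseq2")) {
  engine <- match.arg(engine)
  stopifnot(is(pb, "SummarizedExperiment"))
  cd <- SummarizedExperiment::colData(pb)
  cnt <- SummarizedExperiment::assay(pb, "counts")
  tab <- table(cd$patient, cd$tissue)
  complete <- rownames(tab)[tab[, "normal", drop = TRUE] > 0 &
                            tab[, "tumor", drop = TRUE] > 0]
  if (length(complete) < min_patients)
    stop(sprintf("only %d patient(s) with both tissues; need >= %d",
                 length(complete), min_patients))
  keep <- cd$patient %in% complete
  cnt <- cnt[, keep, drop = FALSE]
  cd <- cd[keep, , drop = FALSE]
  if (engine == "deseq2") return(.pairedDE_deseq2(cnt, cd))

  cpm <- sweep(cnt, 2, colSums(cnt) / 1e6, "/")
  tum <- cpm[, match(paste(complete, "tumor", sep = "."),
                     paste(cd$patient, cd$tissue, sep = ".")), drop = FALSE]
  nor <- cpm[, match(paste(complete, "normal", sep = "."),
                     paste(cd$patient, cd$tissue, sep = ".")), drop = FALSE]
  ratios <- log2((tum + pseudocount) / (nor + pseudocount))
  k <- ncol(ratios)
  lfc <- rowMeans(ratios)
  sdev <- apply(ratios, 1, stats::sd)
  tstat <- lfc / (sdev / sqrt(k))
  p <- 2 * pt(-abs(tstat), df = k - 1)
  # degenerate genes: identical ratio in every patient
  p[sdev == 0 & lfc == 0] <- 1
  p[sdev == 0 & lfc != 0] <- 0
  zero <- rowSums(cnt) == 0
  lfc[zero] <- 0
  p[zero] <- 1
  data.frame(gene_id = rownames(cnt), log2fc = unname(lfc),
             p_value = unname(p),
             direction = ifelse(lfc > 0, "up", "down"),
             is_deg = NA, stringsAsFactors = FALSE)
}

.pairedDE_deseq2 <- function(cnt, cd) {
  if (!requireNamespace("DESeq2", quietly = TRUE))
    stop("engine 'deseq2' requires the DESeq2 package")
  coldat <- data.frame(patient = factor(cd$patient),
                       tissue = factor(cd$tissue, levels = c("normal", "tumor")))
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = as.matrix(cnt),
                                        colData = coldat,
                                        design = ~ patient + tissue)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, contrast = c("tissue", "tumor", "normal"))
  lfc <- res$log2FoldChange
  p <- res$pvalue
  lfc[is.na(lfc)] <- 0
  p[is.na(p)] <- 1
  data.frame(gene_id = rownames(cnt), log2fc = lfc, p_value = p,
             direction = ifelse(lfc > 0, "up", "down"),
             is_deg = NA, stringsAsFactors = FALSE)
}

#' Apply DEG thresholds
#'
#' Flags genes as differentially expressed when `p_value < p_thresh` and
#' `|log2fc| > lfc_thresh`, both strict inequalities. An optional
#' Benjamini-Hochberg mode tests the adjusted p-value instead; the raw
#' p-value is the default reading of the threshold.
#'
#' @param table DEG table from [pairedDE()].
#' @param p_thresh p-value threshold (default 0.05).
#' @param lfc_thresh absolute log2 fold-change threshold (default 0.5).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The table with `is_deg` set (and a `p_adjusted` column when
#'   `adjust = "BH"`).
#' @export
filterDEGs <- function(table, p_thresh = 0.05, lfc_thresh = 0.5,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- table$p_value
  if (adjust == "BH") {
    table$p_adjusted <- p.adjust(p, method = "BH")
    p <- table$p_adjusted
  }
  table$is_deg <- p < p_thresh & abs(table$log2fc) > lfc_thresh
  table
}

#' Summarise a DEG table
#'
#' @param table DEG table with `is_deg` and `direction` set.
#' @return list with `n_total`, `n_up`, `n_down`, `pct_up`, `pct_down`
#'   (percentages to one decimal place).
#' @export
summarizeDEGs <- function(table) {
  deg <- table[!is.na(table$is_deg) & table$is_deg, , drop = FALSE]
  n_up <- sum(deg$direction == "up")
  n_down <- sum(deg$direction == "down")
  n <- n_up + n_down
  list(n_total = n, n_up = n_up, n_down = n_down,
       pct_up = if (n > 0) round(100 * n_up / n, 1) else 0,
       pct_down = if (n > 0) round(100 * n_down / n, 1) else 0)
}
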