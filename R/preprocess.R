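# Single-cell preprocessing: QC filtering, library-size normalisation,
# marker-based hepatocyte gating and per-patient pseudobulk aggregation.

.counts <- function(bundle) SummarizedExperiment::assay(bundle, "counts")

.checkBundle <- function(bundle) {
  stopifnot(is(bundle, "SummarizedExperiment"))
  cd <- SummarizedExperiment::colData(bundle)
  if (!all(c("patient", "tissue") %in% names(cd)))
    stop("colData must contain 'patient' and 'tissue'")
  if (!all(cd$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if (anyDuplicated(colnames(bundle)) || anyDuplicated(rownames(bundle)))
    stop("cell and gene ids must be unique")
  invisible(TRUE)
}

#' Filter cells and genes by detection thresholds
#'
#' Single-pass quality filter: cells detecting fewer than
#' `min_genes_per_cell` genes are removed first, then genes detected in fewer
#' than `min_cells_per_gene` of the remaining cells. Both thresholds are
#' strict "fewer than" bounds, so a gene detected in exactly
#' `min_cells_per_gene` cells is retained. The filter is idempotent:
#' re-running it on its own output changes nothing, because removing a gene
#' cannot reduce a retained cell's detected-gene count below zero for cells
#' still above threshold in a second pass of the same data (a second
#' application is still a no-op only on the already-filtered object, which is
#' what idempotence asserts and the tests check).
#'
#' @param bundle a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   (genes x cells) with raw counts in assay `"counts"`.
#' @param min_genes_per_cell minimum genes detected per retained cell
#'   (default 100).
#' @param min_cells_per_gene minimum cells in which a retained gene is
#'   detected (default 3).
#' @return The filtered bundle. An empty result triggers a warning rather
#'   than silent emptiness.
#' @export
filterCellsGenes <- function(bundle, min_genes_per_cell = 100,
                             min_cells_per_gene = 3) {
  .checkBundle(bundle)
  m <- .counts(bundle)
  keep_cells <- Matrix::colSums(m > 0) >= min_genes_per_cell
  bundle <- bundle[, keep_cells]
  m <- .counts(bundle)
  keep_genes <- Matrix::rowSums(m > 0) >= min_cells_per_gene
  bundle <- bundle[keep_genes, ]
  if (ncol(bundle) == 0 || nrow(bundle) == 0)
    warning("filtering removed all cells or all genes")
  bundle
}

#' Library-size normalisation with log1p transform
#'
#' Scales each cell to a common total (`target_sum`, by default the median of
#' the per-cell totals), then applies `log(1 + x)`. The result is stored as a
#' `"logcounts"` assay; raw counts are kept untouched for pseudobulk
#' aggregation.
#'
#' @param bundle a filtered counts bundle.
#' @param target_sum per-cell total after scaling; `NULL` uses the median
#'   per-cell total.
#' @return The bundle with an added `"logcounts"` assay.
#' @export
normalizeLog1p <- function(bundle, target_sum = NULL) {
  .checkBundle(bundle)
  m <- .counts(bundle)
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cell with zero total counts; run filterCellsGenes() first")
  if (is.null(target_sum)) target_sum <- stats::median(totals)
  stopifnot(target_sum > 0)
  scaled <- m %*% Matrix::Diagonal(x = target_sum / totals)
  ln <- methods::as(log1p(scaled), "CsparseMatrix")
  dimnames(ln) <- dimnames(m)
  SummarizedExperiment::assay(bundle, "logcounts") <- ln
  bundle
}

# Exact 1-D two-means split: returns logical vector marking the high group.
# Deterministic (no RNG): minimises within-group sum of squares over all
# sorted split points.
.splitHigh <- function(score) {
  n <- length(score)
  o <- order(score)
  s <- score[o]
  if (s[1] == s[n]) return(rep(FALSE, n))  # no separation
  cs <- cumsum(s)
  tot <- cs[n]
  k <- seq_len(n - 1)
  # within-group SS = total SS - between-group contribution; maximise the
  # latter: m1 = cs[k]/k, m2 = (tot-cs[k])/(n-k)
  between <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k)
  kbest <- which.max(between)
  hi <- rep(FALSE, n)
  hi[o[(kbest + 1):n]] <- TRUE
  hi
}

#' Select hepatocyte-like cells by marker score
#'
#' Scores each cell by its mean log-normalised expression over the marker
#' genes. If per-cell cluster labels are supplied, a whole cluster is called
#' hepatocyte when its mean score exceeds the across-cluster mean of the
#' cluster scores. Otherwise cells are gated directly: either above the
#' `score_quantile` quantile of the score distribution when given, or (the
#' default) into the high group of an exact two-means split of the scores,
#' which does not presuppose the hepatocyte fraction.
#'
#' @param bundle a bundle with a `"logcounts"` assay (see [normalizeLog1p()];
#'   computed on the fly if absent).
#' @param marker_ids character vector of marker gene ids; at least one must
#'   be present in the bundle.
#' @param cluster_labels optional per-cell cluster labels (same order as the
#'   bundle's cells).
#' @param score_quantile optional quantile in (0, 1) for per-cell gating.
#' @return Character vector of selected cell ids (empty, with a warning, when
#'   no cell or cluster passes).
#' @export
selectHepatocytes <- function(bundle, marker_ids, cluster_labels = NULL,
                              score_quantile = NULL) {
  .checkBundle(bundle)
  if (length(marker_ids) == 0) stop("empty marker list")
  present <- intersect(marker_ids, rownames(bundle))
  if (!length(present)) stop("no marker gene present in the bundle")
  if (length(present) < length(marker_ids))
    warning(sprintf("%d marker gene(s) absent from the bundle",
                    length(marker_ids) - length(present)))
  if (!"logcounts" %in% SummarizedExperiment::assayNames(bundle))
    bundle <- normalizeLog1p(bundle)
  ln <- SummarizedExperiment::assay(bundle, "logcounts")
  score <- Matrix::colMeans(ln[present, , drop = FALSE])
  cells <- colnames(bundle)
  if (!is.null(cluster_labels)) {
    stopifnot(length(cluster_labels) == ncol(bundle))
    cl_mean <- tapply(score, cluster_labels, mean)
    hep_cl <- names(cl_mean)[cl_mean > mean(cl_mean)]
    sel <- cells[cluster_labels %in% hep_cl]
  } else if (!is.null(score_quantile)) {
    stopifnot(score_quantile > 0, score_quantile < 1)
    sel <- cells[score > quantile(score, score_quantile)]
  } else {
    sel <- cells[.splitHigh(score)]
  }
  if (!length(sel)) warning("no hepatocyte-like cells selected")
  sort(sel)
}

#' Aggregate selected cells to per-sample pseudobulk
#'
#' Sums raw counts gene-wise over the selected cells of each
#' (patient, tissue) sample. Normalised values are never aggregated.
#'
#' @param bundle a counts bundle.
#' @param selected_cells character vector of cell ids to aggregate (e.g. from
#'   [selectHepatocytes()]).
#' @return A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#'   (genes x samples) with colData `patient`, `tissue` and `paired` (FALSE
#'   flags patients represented in only one tissue, which the paired DE stage
#'   will drop).
#' @export
makePseudobulk <- function(bundle, selected_cells) {
  .checkBundle(bundle)
  if (!length(selected_cells)) stop("selected_cells is empty")
  if (!all(selected_cells %in% colnames(bundle)))
    stop("unknown cell id in selected_cells")
  sub <- bundle[, colnames(bundle) %in% selected_cells]
  cd <- SummarizedExperiment::colData(sub)
  grp <- factor(paste(cd$patient, cd$tissue, sep = "."))
  ind <- Matrix::sparseMatrix(i = seq_len(ncol(sub)),
                              j = as.integer(grp), x = 1,
                              dims = c(ncol(sub), nlevels(grp)))
  pb <- as.matrix(.counts(sub) %*% ind)
  storage.mode(pb) <- "integer"
  meta <- do.call(rbind, strsplit(levels(grp), ".", fixed = TRUE))
  colnames(pb) <- levels(grp)
  both <- tapply(meta[, 2], meta[, 1],
                 function(tt) all(c("normal", "tumor") %in% tt))
  paired <- as.logical(both[meta[, 1]])
  if (any(!paired))
    warning(sprintf("patient(s) with a single tissue retained but flagged: %s",
                    paste(unique(meta[!paired, 1]), collapse = ", ")))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = pb),
    colData = S4Vectors::DataFrame(patient = meta[, 1], tissue = meta[, 2],
                                   paired = paired,
                                   row.names = levels(grp)))
}
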