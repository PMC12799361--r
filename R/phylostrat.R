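# Phylostratigraphic gene-age enrichment of network genes.

#' Gene-age stratum over-representation of network genes
#'
#' For each evolutionary-age interval, tests whether the network genes
#' over-represent the interval relative to the protein-coding universe using
#' the hypergeometric upper tail: with `N_total` universe genes of which
#' `n_interval` fall in the interval, the probability of observing
#' `m_observed` or more interval genes among the `M_network` network genes is
#' `P(X >= m)`. Intervals are flagged at `p < alpha`, unadjusted by default;
#' a Bonferroni mode over the intervals is available.
#'
#' @param network_genes character vector of network gene ids (subset of
#'   `universe`).
#' @param ages data.frame with `gene_id`, `interval_index`, `interval_label`.
#'   Genes of the universe missing from `ages` are dropped with a warning.
#' @param universe character vector of all protein-coding gene ids.
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default, as reported) or `"bonferroni"`.
#' @return data.frame with one row per interval: `interval_index`,
#'   `interval_label`, `N_total`, `n_interval`, `M_network`, `m_observed`,
#'   `p_value`, `significant`.
#' @export
ageEnrichment <- function(network_genes, ages, universe, alpha = 0.05,
                          adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!length(network_genes)) stop("empty network gene set")
  universe <- unique(universe)
  network_genes <- unique(network_genes)
  if (!all(network_genes %in% universe))
    stop("network_genes must be a subset of the universe")
  if (anyDuplicated(ages$gene_id))
    stop("a gene may occur only once in the age table")
  aged <- ages[ages$gene_id %in% universe, , drop = FALSE]
  n_missing <- length(universe) - nrow(aged)
  if (n_missing > 0)
    warning(sprintf("%d universe gene(s) without age assignment dropped",
                    n_missing))
  N_total <- nrow(aged)
  net_aged <- aged[aged$gene_id %in% network_genes, , drop = FALSE]
  M_network <- nrow(net_aged)
  if (M_network == 0) stop("no network gene has an age assignment")
  ivs <- sort(unique(aged$interval_index))
  lab <- vapply(ivs, function(i)
    aged$interval_label[match(i, aged$interval_index)], character(1))
  n_interval <- vapply(ivs, function(i)
    sum(aged$interval_index == i), integer(1))
  m_observed <- vapply(ivs, function(i)
    sum(net_aged$interval_index == i), integer(1))
  p <- vapply(seq_along(ivs), function(j)
    hypergeomUpperTail(N_total, n_interval[j], M_network, m_observed[j]),
    numeric(1))
  p_use <- if (adjust == "bonferroni") pmin(1, p * length(p)) else p
  res <- data.frame(interval_index = ivs, interval_label = lab,
                    N_total = N_total, n_interval = n_interval,
                    M_network = M_network, m_observed = m_observed,
                    p_value = p, significant = p_use < alpha,
                    stringsAsFactors = FALSE)
  if (adjust == "bonferroni") res$p_bonferroni <- p_use
  rownames(res) <- NULL
  res
}
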