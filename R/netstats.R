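#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= x)` where `X` follows a hypergeometric distribution with
#' population size `M`, of which `n` are "network" genes, and `N` draws (the
#' genes a protein interacts with genome-wide). This is the
#' interaction-specificity statistic used to decide whether a protein's
#' partners are over-represented inside an analysed network: `M` is the total
#' number of protein-coding genes in the database, `n` the number of genes in
#' the analysed network, `N` the total number of genes interacting with the
#' protein under study, and `x` the number of network genes among them.
#'
#' The sum is evaluated in log space (`lchoose` plus a log-sum-exp reduction)
#' so that large `M` do not underflow.
#'
#' @param M population size (total protein-coding genes in the database).
#' @param n number of network genes, `n <= M`.
#' @param N number of draws (protein's genome-wide interaction partners),
#'   `N <= M`.
#' @param x observed number of network genes among the `N` partners,
#'   `0 <= x <= min(n, N)`.
#' @return `P(X >= x)`, a probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeomUpperTail(10, 4, 3, 2)  # 40/120
hypergeomUpperTail <- function(M, n, N, x) {
  stopifnot(length(M) == 1, length(n) == 1, length(N) == 1, length(x) == 1)
  if (any(c(M, n, N, x) < 0) || any(c(M, n, N, x) != floor(c(M, n, N, x))))
    stop("M, n, N, x must be non-negative integers")
  if (n > M || N > M) stop("n and N must not exceed M")
  if (x > min(n, N)) stop("x must not exceed min(n, N)")
  if (x == 0) return(1)
  ks <- seq.int(x, min(n, N))
  lt <- lchoose(n, ks) + lchoose(M - n, N - ks) - lchoose(M, N)
  lt <- lt[is.finite(lt)]
  if (!length(lt)) return(0)
  mx <- max(lt)
  min(exp(mx + log(sum(exp(lt - mx)))), 1)
}

.hypergeomUpperTailVec <- function(M, n, N, x) {
  vapply(seq_along(x),
         function(i) hypergeomUpperTail(M, n, N[i], x[i]),
         numeric(1))
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests and caps at 1.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bonferroniAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "bonferroni")
}

#' Sidak adjustment
#'
#' Maps each p-value to `1 - (1 - p)^k` with `k = length(p)`, the familywise
#' correction used for term over-representation reports.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
sidakAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  pmin(1, 1 - (1 - p)^length(p))
}

#' One-sided gene-set over-representation test
#'
#' One-sided Fisher test (equivalently, the hypergeometric upper tail) on the
#' 2x2 membership table of a query gene set against a term gene set within a
#' universe.
#'
#' @param query character vector of query gene ids (subset of `universe`).
#' @param term_genes character vector of term gene ids (subset of `universe`).
#' @param universe character vector of all gene ids.
#' @return Raw one-sided p-value for over-representation; multiplicity
#'   correction (e.g. [sidakAdjust()]) is the caller's responsibility.
#' @export
geneSetOverrep <- function(query, term_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  term_genes <- unique(term_genes)
  if (!all(query %in% universe) || !all(term_genes %in% universe))
    stop("query and term_genes must be subsets of the universe")
  x <- length(intersect(query, term_genes))
  hypergeomUpperTail(length(universe), length(term_genes), length(query), x)
}

#' Interaction-specificity test for candidate regulators
#'
#' For each candidate protein, tests whether its interaction partners are
#' over-represented among the genes of the analysed network. Per candidate:
#' `N` is the number of distinct genes it touches genome-wide through the
#' four edge types (protein-protein interaction edges mapped to the partner
#' protein's gene, the protein's own gene excluded), `x` the number of
#' distinct network genes among them, `n` the number of gene nodes in the
#' network and `M` the size of the gene universe. The raw p-value is the
#' hypergeometric upper tail `P(X >= x)`; Bonferroni correction is applied
#' over the number of candidates tested.
#'
#' @param candidates candidate table as returned by
#'   [findCandidateRegulators()].
#' @param net the stage-1 [GeneNetwork-class].
#' @param kg the full [KnowledgeGraph-class].
#' @param M gene universe size; defaults to the number of distinct gene nodes
#'   in `kg` (the database's protein-coding universe when known should be
#'   supplied instead).
#' @param alpha familywise significance level for the `significant` flag.
#' @return data.frame with one row per candidate, sorted by ascending raw
#'   p-value: `protein_id`, `M`, `n`, `N`, `x`, `p_raw`, `p_bonferroni`,
#'   `significant`.
#' @export
specificityTest <- function(candidates, net, kg, M = NULL, alpha = 0.05) {
  stopifnot(is(net, "GeneNetwork"), is(kg, "KnowledgeGraph"))
  if (is.null(M)) M <- length(geneIds(kg))
  if (M < length(geneIds(kg)))
    stop("M must be at least the number of distinct genes in the knowledge graph")
  net_genes <- geneIds(net)
  n <- length(net_genes)
  if (nrow(candidates) == 0) {
    return(data.frame(protein_id = character(0), M = integer(0),
                      n = integer(0), N = integer(0), x = integer(0),
                      p_raw = numeric(0), p_bonferroni = numeric(0),
                      significant = logical(0)))
  }
  targ_all <- .proteinTargets(kg, candidates$protein_id)
  N <- lengths(targ_all)
  x <- vapply(targ_all, function(tg) sum(tg %in% net_genes), integer(1))
  keep <- N > 0
  if (any(!keep))
    warning(sprintf("%d candidate(s) with no genome-wide interactions excluded",
                    sum(!keep)))
  ids <- candidates$protein_id[keep]
  N <- N[keep]; x <- x[keep]
  p_raw <- .hypergeomUpperTailVec(M, n, N, x)
  p_bonf <- pmin(1, p_raw * length(p_raw))
  res <- data.frame(protein_id = ids, M = M, n = n, N = N, x = x,
                    p_raw = p_raw, p_bonferroni = p_bonf,
                    significant = p_bonf < alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_raw, res$protein_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Network connectivity (degree) of every node
#'
#' Connectivity of a node is the number of other network nodes it is
#' connected to: parallel edges of different types count the neighbour once
#' and self-loops are excluded.
#'
#' @param net a [GeneNetwork-class].
#' @return data.frame with columns `node_id`, `kind`, `connectivity`, one row
#'   per network node (isolated nodes have connectivity 0).
#' @export
nodeConnectivity <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  nd <- netNodes(net)
  ed <- netEdges(net)
  deg <- setNames(integer(nrow(nd)), nd$node_id)
  if (nrow(ed) > 0) {
    a <- pmin(ed$source, ed$target)
    b <- pmax(ed$source, ed$target)
    keep <- a != b
    pairs <- unique(data.frame(a = a[keep], b = b[keep]))
    tt <- table(c(pairs$a, pairs$b))
    deg[names(tt)] <- as.integer(tt)
  }
  data.frame(node_id = nd$node_id, kind = nd$kind,
             connectivity = as.integer(deg), stringsAsFactors = FALSE)
}

#' Detect network hubs by empirical degree quantile
#'
#' Hubs are nodes whose connectivity strictly exceeds the critical value: the
#' empirical `1 - alpha` quantile (nearest-rank) of the connectivity
#' distribution pooled over all network nodes (genes and proteins together).
#'
#' @param degrees degree table from [nodeConnectivity()], or a named integer
#'   vector of per-node degrees.
#' @param alpha tail probability defining the critical quantile
#'   (default 0.05).
#' @return A list of class `HubReport`: `connectivity` (named vector),
#'   `critical_value`, `hubs` (node ids, sorted), `alpha`.
#' @export
detectHubs <- function(degrees, alpha = 0.05) {
  if (is.data.frame(degrees)) {
    deg <- setNames(as.integer(degrees$connectivity), degrees$node_id)
  } else {
    deg <- degrees
  }
  if (length(deg) < 2) stop("need at least 2 nodes to define a hub quantile")
  if (is.null(names(deg))) stop("degrees must be named by node id")
  critical <- as.numeric(quantile(deg, probs = 1 - alpha, type = 1,
                                  names = FALSE))
  hubs <- sort(names(deg)[deg > critical])
  structure(list(connectivity = deg, critical_value = critical,
                 hubs = hubs, alpha = alpha),
            class = "HubReport")
}

#' @export
print.HubReport <- function(x, ...) {
  cat(sprintf("HubReport: %d nodes, critical connectivity %g (alpha = %g)\n",
              length(x$connectivity), x$critical_value, x$alpha))
  cat(sprintf("  %d hub(s): %s\n", length(x$hubs),
              paste(utils::head(x$hubs, 10), collapse = ", ")))
  invisible(x)
}
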