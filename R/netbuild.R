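# Two-stage network construction over a typed knowledge graph.

# Map each outgoing edge of a protein to the gene it reaches: gene targets
# map to themselves, protein targets (interaction edges) to the gene the
# partner protein encodes. The protein's own gene is excluded, so
# self-regulation never qualifies a candidate nor inflates its counts.
.proteinTargets <- function(kg, protein_ids) {
  nd <- kgNodes(kg)
  ed <- kgEdges(kg)
  encodes <- setNames(nd$encodes, nd$node_id)
  kind <- setNames(nd$kind, nd$node_id)
  ed <- ed[ed$source %in% protein_ids, , drop = FALSE]
  tgt_gene <- ifelse(kind[ed$target] == "gene", ed$target,
                     encodes[ed$target])
  own_gene <- encodes[ed$source]
  keep <- tgt_gene != own_gene
  src <- ed$source[keep]
  tgt_gene <- tgt_gene[keep]
  out <- lapply(split(tgt_gene, factor(src, levels = protein_ids)),
                function(v) sort(unique(v)))
  names(out) <- protein_ids
  out
}

.inducedEdges <- function(kg, node_ids) {
  ed <- kgEdges(kg)
  ed[ed$source %in% node_ids & ed$target %in% node_ids, , drop = FALSE]
}

#' Stage-1 seed network
#'
#' Builds the seed network: the genes of the seed set that are differentially
#' expressed, their protein products, and all knowledge-graph edges induced
#' by that node set.
#'
#' @param degs DEG table (see [pairedDE()]) with `gene_id` and `is_deg`.
#' @param seed_set character vector of seed gene ids (e.g. a GO term's
#'   gene list).
#' @param kg a [KnowledgeGraph-class].
#' @return A stage-1 [GeneNetwork-class]. An empty intersection of seed set
#'   and DEGs yields an empty network with a warning.
#' @export
seedNetwork <- function(degs, seed_set, kg) {
  stopifnot(is(kg, "KnowledgeGraph"), length(seed_set) > 0)
  nd <- kgNodes(kg)
  deg_genes <- degs$gene_id[degs$is_deg]
  net_genes <- sort(intersect(intersect(seed_set, deg_genes),
                              nd$node_id[nd$kind == "gene"]))
  if (!length(net_genes)) {
    warning("no seed-set gene is differentially expressed: empty seed network")
    return(GeneNetwork(.emptyNodes(), .emptyEdges(), stage = "stage1",
                       metadata = list(seed_set = sort(unique(seed_set)))))
  }
  prots <- nd[nd$kind == "protein" & nd$encodes %in% net_genes, , drop = FALSE]
  nodes <- rbind(nd[nd$node_id %in% net_genes, , drop = FALSE], prots)
  GeneNetwork(nodes, .inducedEdges(kg, nodes$node_id), stage = "stage1",
              metadata = list(seed_set = sort(unique(seed_set))))
}

#' Find candidate regulator proteins
#'
#' Candidates are proteins whose encoding gene is differentially expressed
#' but absent from the seed network, and which have at least one edge of the
#' four relationship types reaching a network gene (protein-protein
#' interaction edges are mapped to the partner's gene; a protein's edges to
#' its own gene never count).
#'
#' @param degs DEG table with `gene_id` and `is_deg`.
#' @param net stage-1 [GeneNetwork-class].
#' @param kg a [KnowledgeGraph-class].
#' @return data.frame with one row per candidate: `protein_id`, `gene_id`
#'   (encoding gene), `n_targets`, and a list column `targets` holding the
#'   distinct network genes each candidate reaches.
#' @export
findCandidateRegulators <- function(degs, net, kg) {
  stopifnot(is(net, "GeneNetwork"), is(kg, "KnowledgeGraph"))
  nd <- kgNodes(kg)
  deg_genes <- degs$gene_id[degs$is_deg]
  net_genes <- geneIds(net)
  net_nodes <- netNodes(net)$node_id
  cand <- nd[nd$kind == "protein" &
               nd$encodes %in% deg_genes &
               !(nd$node_id %in% net_nodes), , drop = FALSE]
  cand <- cand[order(cand$node_id), , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(protein_id = character(0), gene_id = character(0),
                      n_targets = integer(0),
                      targets = I(list())))
  }
  targ <- .proteinTargets(kg, cand$node_id)
  net_targ <- lapply(targ, function(tg) tg[tg %in% net_genes])
  keep <- lengths(net_targ) > 0
  out <- data.frame(protein_id = cand$node_id[keep],
                    gene_id = cand$encodes[keep],
                    n_targets = lengths(net_targ)[keep],
                    stringsAsFactors = FALSE)
  out$targets <- I(unname(net_targ[keep]))
  rownames(out) <- NULL
  out
}

#' Assemble the final (stage-2) network
#'
#' Adds the significant candidate regulator proteins to the stage-1 node set
#' and re-induces edges from the knowledge graph.
#'
#' @param net stage-1 [GeneNetwork-class].
#' @param significant character vector of significant candidate protein ids
#'   (typically `subset(specificityTest(...), significant)$protein_id`).
#' @param kg a [KnowledgeGraph-class].
#' @return A stage-2 [GeneNetwork-class] whose node count equals the stage-1
#'   node count plus `length(significant)`.
#' @export
assembleFinalNetwork <- function(net, significant, kg) {
  stopifnot(is(net, "GeneNetwork"), is(kg, "KnowledgeGraph"))
  nd <- kgNodes(kg)
  significant <- unique(significant)
  if (!all(significant %in% nd$node_id[nd$kind == "protein"]))
    stop("significant ids must be protein nodes of the knowledge graph")
  if (any(significant %in% netNodes(net)$node_id))
    stop("significant candidates must be disjoint from the stage-1 network")
  nodes <- rbind(netNodes(net)[, c("node_id", "kind", "encodes")],
                 nd[nd$node_id %in% significant, , drop = FALSE])
  GeneNetwork(nodes, .inducedEdges(kg, nodes$node_id), stage = "stage2",
              metadata = c(net@metadata,
                           list(significant_regulators = sort(significant))))
}

#' Edge census by relationship type
#'
#' @param net a [GeneNetwork-class].
#' @return Named integer vector with one entry per edge type plus `total`.
#' @export
edgeCensus <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  tt <- table(factor(netEdges(net)$type, levels = edgeTypes()))
  out <- as.integer(tt)
  names(out) <- edgeTypes()
  c(out, total = sum(out))
}

#' Direction-filtered regulation subnetwork
#'
#' Restricts a (typically stage-2) network to edges of a single
#' expression-regulatory direction - activation (`"upregulation"`) or
#' repression (`"downregulation"`) - and to the nodes those edges touch. Each
#' retained node is annotated with its gene's differential-expression
#' direction (protein nodes inherit the direction of their encoding gene).
#'
#' @param net a [GeneNetwork-class].
#' @param direction `"upregulation"` or `"downregulation"`.
#' @param degs DEG table with `gene_id`, `direction`, `is_deg`.
#' @return A [GeneNetwork-class] whose nodes carry an `expression` column
#'   (`"up"`, `"down"` or `NA`); its metadata records the filtered direction.
#' @export
regulationSubnetwork <- function(net, direction = c("upregulation",
                                                    "downregulation"),
                                 degs) {
  stopifnot(is(net, "GeneNetwork"))
  direction <- match.arg(direction)
  type <- paste0("expression_", direction)
  ed <- netEdges(net)
  ed <- ed[ed$type == type, , drop = FALSE]
  nd <- netNodes(net)
  nd <- nd[nd$node_id %in% c(ed$source, ed$target),
           c("node_id", "kind", "encodes"), drop = FALSE]
  gene_of <- ifelse(nd$kind == "gene", nd$node_id, nd$encodes)
  dir_of <- setNames(ifelse(degs$is_deg, degs$direction, NA_character_),
                     degs$gene_id)
  nd$expression <- unname(dir_of[gene_of])
  GeneNetwork(nd, ed, stage = netStage(net),
              metadata = list(direction = direction))
}
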