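# Small in-code fixtures shared across the test files.

# A dense counts bundle built by hand: genes x cells with patient/tissue
# labels. `mat` rows are genes, columns cells.
makeBundle <- function(mat, patient, tissue, gene_ids = NULL,
                       cell_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(mat)))
  if (is.null(cell_ids)) cell_ids <- sprintf("c%03d", seq_len(ncol(mat)))
  dimnames(mat) <- list(gene_ids, cell_ids)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(mat, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(patient = patient, tissue = tissue,
                                   row.names = cell_ids))
}

# A small hand-written knowledge graph: genes gA..gE with proteins, a few
# typed edges.
tinyKG <- function() {
  genes <- paste0("g", LETTERS[1:5])
  nodes <- rbind(
    data.frame(node_id = genes, kind = "gene", encodes = NA_character_),
    data.frame(node_id = paste0(genes, "_prot"), kind = "protein",
               encodes = genes))
  edges <- data.frame(
    source = c("gA_prot", "gA_prot", "gB_prot", "gC_prot", "gD_prot",
               "gE_prot"),
    target = c("gB", "gC", "gA", "gA_prot", "gE", "gA"),
    type = c("expression_upregulation", "expression_downregulation",
             "expression_regulation", "interaction",
             "expression_regulation", "expression_upregulation"),
    stringsAsFactors = FALSE)
  KnowledgeGraph(nodes, edges)
}

# DEG table stub.
degTable <- function(gene_ids, deg_ids = gene_ids, up_ids = deg_ids) {
  data.frame(gene_id = gene_ids,
             log2fc = ifelse(gene_ids %in% up_ids, 1, -1),
             p_value = ifelse(gene_ids %in% deg_ids, 0.001, 0.9),
             direction = ifelse(gene_ids %in% up_ids, "up", "down"),
             is_deg = gene_ids %in% deg_ids,
             stringsAsFactors = FALSE)
}

# A GeneNetwork of plain gene nodes from an undirected edge list, used for
# degree/hub tests.
plainNetwork <- function(edge_df, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- unique(c(edge_df$source, edge_df$target))
  nodes <- data.frame(node_id = node_ids, kind = "gene",
                      encodes = NA_character_, stringsAsFactors = FALSE)
  if (!"type" %in% names(edge_df)) edge_df$type <- "interaction"
  GeneNetwork(nodes, edge_df, stage = "stage2")
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail: lists all
# C(M, N) draws of N items from a population of M with n successes and counts
# how many contain at least x successes. Independent of the package's
# log-space implementation.
enumUpperTail <- function(M, n, N, x) {
  if (x == 0) return(1)
  if (N == 0) return(0)
  pop <- c(rep(1, n), rep(0, M - n))
  draws <- utils::combn(M, N)
  hits <- colSums(matrix(pop[draws], nrow = N))
  mean(hits >= x)
}

# Largest achievable rejection level below `alpha` for the discrete
# upper-tail test with parameters (M, n, N): the tail probability at the
# smallest x whose tail falls under alpha.
attainableLevel <- function(M, n, N, alpha = 0.05) {
  for (x in 0:min(n, N)) {
    p <- scSeedNet::hypergeomUpperTail(M, n, N, x)
    if (p < alpha) return(p)
  }
  0
}
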