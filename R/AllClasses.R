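#' @import methods
#' @importFrom stats rnbinom rnorm rbinom pt quantile setNames p.adjust
#' @importFrom utils read.delim write.table
NULL

#' Edge types recognised in a knowledge graph
#'
#' The four relationship types used throughout the package: the three
#' expression-regulatory types (which always run protein -> gene) and the
#' generic `interaction` type (which may also connect two proteins).
#'
#' @return Character vector of the four edge-type names.
#' @export
#' @examples
#' edgeTypes()
edgeTypes <- function() {
  c("expression_regulation", "expression_upregulation",
    "expression_downregulation", "interaction")
}

.REGULATORY_TYPES <- c("expression_regulation", "expression_upregulation",
                       "expression_downregulation")

.emptyNodes <- function() {
  data.frame(node_id = character(0), kind = character(0),
              encodes = character(0), stringsAsFactors = FALSE)
}

.emptyEdges <- function() {
  data.frame(source = character(0), target = character(0),
              type = character(0), stringsAsFactors = FALSE)
}

#' KnowledgeGraph class
#'
#' A typed directed graph of gene and protein entities. Gene nodes carry
#' `encodes = NA`; protein nodes name the single gene that encodes them.
#' Edges carry one of the four types in [edgeTypes()]. Expression-regulatory
#' edges must run protein -> gene; `interaction` edges may connect a protein
#' to a gene or to another protein.
#'
#' @slot nodes data.frame with columns `node_id`, `kind` ("gene"/"protein"),
#'   `encodes` (gene id for proteins, `NA` for genes).
#' @slot edges data.frame with columns `source`, `target`, `type`.
#' @export
setClass("KnowledgeGraph",
         slots = c(nodes = "data.frame", edges = "data.frame"),
         prototype = prototype(nodes = .emptyNodes(), edges = .emptyEdges()))

setValidity("KnowledgeGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character(0)
  need_n <- c("node_id", "kind", "encodes")
  need_e <- c("source", "target", "type")
  if (!all(need_n %in% names(nd)))
    return(sprintf("nodes must have columns %s", paste(need_n, collapse = ", ")))
  if (!all(need_e %in% names(ed)))
    return(sprintf("edges must have columns %s", paste(need_e, collapse = ", ")))
  if (anyDuplicated(nd$node_id))
    msgs <- c(msgs, "duplicate node ids")
  if (!all(nd$kind %in% c("gene", "protein")))
    msgs <- c(msgs, "node kind must be 'gene' or 'protein'")
  is_prot <- nd$kind == "protein"
  if (any(is.na(nd$encodes[is_prot])))
    msgs <- c(msgs, "every protein must encode exactly one gene")
  gene_ids <- nd$node_id[nd$kind == "gene"]
  if (!all(nd$encodes[is_prot] %in% gene_ids))
    msgs <- c(msgs, "protein 'encodes' must reference an existing gene node")
  if (!all(is.na(nd$encodes[!is_prot])))
    msgs <- c(msgs, "gene nodes must have encodes = NA")
  if (nrow(ed) > 0) {
    if (!all(ed$type %in% edgeTypes()))
      msgs <- c(msgs, "unknown edge type")
    if (!all(c(ed$source, ed$target) %in% nd$node_id))
      msgs <- c(msgs, "edge endpoint not present among nodes")
    kind_of <- setNames(nd$kind, nd$node_id)
    reg <- ed$type %in% .REGULATORY_TYPES
    if (any(reg) &&
        (!all(kind_of[ed$source[reg]] == "protein") ||
         !all(kind_of[ed$target[reg]] == "gene")))
      msgs <- c(msgs, "expression-regulatory edges must run protein -> gene")
    if (anyDuplicated(ed[, c("source", "target", "type")]))
      msgs <- c(msgs, "duplicate (source, target, type) edges")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

.canonNodes <- function(nodes) {
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

.canonEdges <- function(edges) {
  edges <- unique(edges[, c("source", "target", "type")])
  edges <- edges[order(edges$source, edges$target, edges$type), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Construct a KnowledgeGraph
#'
#' Canonicalises input (sorted nodes and edges, duplicate same-type edges
#' collapsed) so that construction is deterministic, then validates the
#' typing rules described in [KnowledgeGraph-class].
#'
#' @param nodes data.frame with columns `node_id`, `kind`, `encodes`.
#' @param edges data.frame with columns `source`, `target`, `type`.
#' @return A [KnowledgeGraph-class] object.
#' @export
#' @examples
#' nodes <- data.frame(node_id = c("g1", "g1_prot"),
#'                     kind = c("gene", "protein"),
#'                     encodes = c(NA, "g1"))
#' edges <- data.frame(source = "g1_prot", target = "g1",
#'                     type = "expression_regulation")
#' KnowledgeGraph(nodes, edges)
KnowledgeGraph <- function(nodes, edges = .emptyEdges()) {
  nodes$encodes <- as.character(nodes$encodes)
  new("KnowledgeGraph", nodes = .canonNodes(nodes), edges = .canonEdges(edges))
}

#' GeneNetwork class
#'
#' A network extracted from a [KnowledgeGraph-class]: a node subset together
#' with its induced typed edges and a stage tag (`"stage1"` for the seed
#' network of differentially expressed seed-set genes plus their protein
#' products, `"stage2"` after expansion with significant candidate
#' regulators). Extra node annotation columns (for example the expression
#' direction added by [regulationSubnetwork()]) are carried in `nodes`.
#'
#' @slot nodes data.frame with at least `node_id`, `kind`, `encodes`.
#' @slot edges data.frame with `source`, `target`, `type`.
#' @slot stage character scalar, `"stage1"` or `"stage2"`.
#' @slot metadata list of free-form annotations (for example the edge-type
#'   direction of a regulation subnetwork).
#' @export
setClass("GeneNetwork",
         slots = c(nodes = "data.frame", edges = "data.frame",
                   stage = "character", metadata = "list"),
         prototype = prototype(nodes = .emptyNodes(), edges = .emptyEdges(),
                               stage = "stage1", metadata = list()))

setValidity("GeneNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("node_id", "kind", "encodes") %in% names(nd)))
    return("nodes must have columns node_id, kind, encodes")
  if (length(object@stage) != 1L || !object@stage %in% c("stage1", "stage2"))
    return("stage must be 'stage1' or 'stage2'")
  if (anyDuplicated(nd$node_id))
    return("duplicate node ids")
  if (nrow(ed) > 0 && !all(c(ed$source, ed$target) %in% nd$node_id))
    return("edge endpoint not present among network nodes")
  TRUE
})

#' Construct a GeneNetwork
#'
#' @param nodes data.frame of nodes (`node_id`, `kind`, `encodes`, plus any
#'   annotation columns).
#' @param edges data.frame of typed edges.
#' @param stage `"stage1"` or `"stage2"`.
#' @param metadata optional list of annotations.
#' @return A [GeneNetwork-class] object with canonically ordered nodes/edges.
#' @export
GeneNetwork <- function(nodes, edges = .emptyEdges(), stage = "stage1",
                        metadata = list()) {
  nodes$encodes <- as.character(nodes$encodes)
  new("GeneNetwork", nodes = .canonNodes(nodes), edges = .canonEdges(edges),
      stage = stage, metadata = metadata)
}

# ---- generics ---------------------------------------------------------------

#' Accessors for graph and network objects
#'
#' `kgNodes()`/`kgEdges()` return the node and edge tables of a
#' [KnowledgeGraph-class]; `netNodes()`/`netEdges()`/`netStage()` the
#' corresponding pieces of a [GeneNetwork-class]. `geneIds()` and
#' `proteinIds()` return the ids of gene or protein nodes of either class.
#'
#' @param x A `KnowledgeGraph` or `GeneNetwork`.
#' @return A data.frame (node/edge accessors) or character vector (id
#'   accessors).
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
setGeneric("kgNodes", function(x) standardGeneric("kgNodes"))
#' @rdname graph-accessors
#' @export
setGeneric("kgEdges", function(x) standardGeneric("kgEdges"))
#' @rdname graph-accessors
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))
#' @rdname graph-accessors
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))
#' @rdname graph-accessors
#' @export
setGeneric("netStage", function(x) standardGeneric("netStage"))
#' @rdname graph-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname graph-accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname graph-accessors
setMethod("kgNodes", "KnowledgeGraph", function(x) x@nodes)
#' @rdname graph-accessors
setMethod("kgEdges", "KnowledgeGraph", function(x) x@edges)
#' @rdname graph-accessors
setMethod("netNodes", "GeneNetwork", function(x) x@nodes)
#' @rdname graph-accessors
setMethod("netEdges", "GeneNetwork", function(x) x@edges)
#' @rdname graph-accessors
setMethod("netStage", "GeneNetwork", function(x) x@stage)
#' @rdname graph-accessors
setMethod("geneIds", "KnowledgeGraph",
          function(x) x@nodes$node_id[x@nodes$kind == "gene"])
#' @rdname graph-accessors
setMethod("geneIds", "GeneNetwork",
          function(x) x@nodes$node_id[x@nodes$kind == "gene"])
#' @rdname graph-accessors
setMethod("proteinIds", "KnowledgeGraph",
          function(x) x@nodes$node_id[x@nodes$kind == "protein"])
#' @rdname graph-accessors
setMethod("proteinIds", "GeneNetwork",
          function(x) x@nodes$node_id[x@nodes$kind == "protein"])

setMethod("show", "KnowledgeGraph", function(object) {
  tt <- table(factor(object@edges$type, levels = edgeTypes()))
  cat(sprintf("KnowledgeGraph: %d genes, %d proteins, %d edges\n",
              sum(object@nodes$kind == "gene"),
              sum(object@nodes$kind == "protein"),
              nrow(object@edges)))
  for (nm in names(tt)) cat(sprintf("  %-28s %d\n", nm, tt[[nm]]))
  invisible(NULL)
})

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork [%s]: %d genes, %d proteins, %d edges\n",
              object@stage,
              sum(object@nodes$kind == "gene"),
              sum(object@nodes$kind == "protein"),
              nrow(object@edges)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  invisible(NULL)
})
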