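# Readers and writers for the plain-text interchange formats: 10x-style MTX
# triplets with a cell-metadata TSV, GMT gene sets, typed knowledge-graph
# edge lists, gene-age tables, pseudobulk and DEG tables, and GraphML export.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, required, what) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s in %s", what,
                 paste(missing, collapse = ", "), path))
  df
}

#' Write and read a counts bundle as 10x-style text files
#'
#' `writeCountsBundle()` writes `matrix.mtx` (MatrixMarket, genes x cells),
#' `genes.tsv`, `barcodes.tsv` and `cell_meta.tsv` (cell_id, patient, tissue,
#' optional cluster) into `dir`. `readCountsBundle()` reads them back into a
#' [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment];
#' integer counts round-trip exactly.
#'
#' @param bundle a counts bundle (genes x cells SingleCellExperiment).
#' @param dir directory to write to / read from (created if needed).
#' @return `writeCountsBundle()` returns `dir` invisibly;
#'   `readCountsBundle()` returns the bundle.
#' @export
writeCountsBundle <- function(bundle, dir) {
  .checkBundle(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- .counts(bundle)
  Matrix::writeMM(methods::as(m, "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(bundle), file.path(dir, "genes.tsv"))
  writeLines(colnames(bundle), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(bundle))
  meta <- cbind(data.frame(cell_id = colnames(bundle),
                           stringsAsFactors = FALSE), cd)
  .write_tsv(meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' @rdname writeCountsBundle
#' @export
readCountsBundle <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  if (anyDuplicated(genes)) stop("duplicate gene id in genes.tsv")
  if (anyDuplicated(cells)) stop("duplicate cell id in barcodes.tsv")
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("matrix dimensions do not match genes.tsv/barcodes.tsv")
  dimnames(m) <- list(genes, cells)
  meta <- .read_tsv(file.path(dir, "cell_meta.tsv"),
                    c("cell_id", "patient", "tissue"), "cell_meta")
  if (!identical(meta$cell_id, cells))
    meta <- meta[match(cells, meta$cell_id), , drop = FALSE]
  if (anyNA(meta$cell_id)) stop("cell_meta.tsv does not cover all barcodes")
  cd <- S4Vectors::DataFrame(meta[, setdiff(names(meta), "cell_id"),
                                  drop = FALSE], row.names = cells)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m),
                                             colData = cd)
}

#' Write and read GMT gene-set files
#'
#' One set per line: set name, description, then tab-separated gene ids. The
#' description field is preserved on write (`"na"` by default) and tolerated
#' on read.
#'
#' @param sets named list of character vectors of gene ids.
#' @param path file path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `readGMT()` returns a named list of character vectors.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGMT
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT line(s) %s in %s (need name, description, ",
                 paste(bad, collapse = ", "), path),
         ">= 1 gene)")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set name in GMT")
  sets
}

#' Write and read a knowledge graph as TSV tables
#'
#' The edge list carries `source_id`, `source_kind`, `target_id`,
#' `target_kind`, `edge_type`; a companion `<path>.nodes.tsv` carries the
#' full node table (including isolated nodes and the protein-to-gene encoding
#' map). Unknown edge types and dangling node ids are reported as errors on
#' read.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param path path of the edge-list TSV; the node table goes to
#'   `paste0(path, ".nodes.tsv")`.
#' @return `readKnowledgeGraph()` returns a [KnowledgeGraph-class].
#' @export
writeKnowledgeGraph <- function(kg, path) {
  stopifnot(is(kg, "KnowledgeGraph"))
  nd <- kgNodes(kg)
  ed <- kgEdges(kg)
  kind_of <- setNames(nd$kind, nd$node_id)
  .write_tsv(data.frame(source_id = ed$source,
                        source_kind = unname(kind_of[ed$source]),
                        target_id = ed$target,
                        target_kind = unname(kind_of[ed$target]),
                        edge_type = ed$type, stringsAsFactors = FALSE),
             path)
  .write_tsv(nd, paste0(path, ".nodes.tsv"))
  invisible(path)
}

#' @rdname writeKnowledgeGraph
#' @export
readKnowledgeGraph <- function(path) {
  ed <- .read_tsv(path, c("source_id", "source_kind", "target_id",
                          "target_kind", "edge_type"), "knowledge graph")
  bad <- which(!ed$edge_type %in% edgeTypes())
  if (length(bad))
    stop(sprintf("unknown edge type at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path))
  nodes_path <- paste0(path, ".nodes.tsv")
  if (file.exists(nodes_path)) {
    nd <- .read_tsv(nodes_path, c("node_id", "kind", "encodes"), "nodes")
  } else {
    # reconstruct nodes from edge endpoints; protein encoding inferred from
    # the '<gene>_prot' id convention
    ids <- unique(c(ed$source_id, ed$target_id))
    kinds <- c(setNames(ed$source_kind, ed$source_id),
               setNames(ed$target_kind, ed$target_id))
    kind <- unname(kinds[ids])
    nd <- data.frame(node_id = ids, kind = kind,
                     encodes = ifelse(kind == "protein",
                                      sub("_prot$", "", ids), NA_character_),
                     stringsAsFactors = FALSE)
  }
  dangling <- setdiff(c(ed$source_id, ed$target_id), nd$node_id)
  if (length(dangling))
    stop(sprintf("dangling node id(s) in %s: %s", path,
                 paste(utils::head(dangling, 5), collapse = ", ")))
  KnowledgeGraph(nd, data.frame(source = ed$source_id, target = ed$target_id,
                                type = ed$edge_type, stringsAsFactors = FALSE))
}

#' Write and read a gene-age table
#'
#' TSV with columns `gene_id`, `interval_index`, `interval_label`.
#'
#' @param ages data.frame with the three columns above.
#' @param path file path.
#' @return `readAgeTable()` returns the data.frame.
#' @export
writeAgeTable <- function(ages, path) {
  .write_tsv(ages[, c("gene_id", "interval_index", "interval_label")], path)
  invisible(path)
}

#' @rdname writeAgeTable
#' @export
readAgeTable <- function(path) {
  df <- .read_tsv(path, c("gene_id", "interval_index", "interval_label"),
                  "age table")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene id in age table")
  df$interval_index <- as.integer(df$interval_index)
  df
}

#' Write and read pseudobulk tables
#'
#' `<path>` holds the sample x gene count table (rows = samples); a companion
#' `<path>.meta.tsv` holds `sample_id`, `patient`, `tissue`.
#'
#' @param pb pseudobulk SummarizedExperiment from [makePseudobulk()].
#' @param path file path of the counts TSV.
#' @return `readPseudobulk()` returns the SummarizedExperiment.
#' @export
writePseudobulk <- function(pb, path) {
  cnt <- t(SummarizedExperiment::assay(pb, "counts"))
  df <- cbind(data.frame(sample_id = rownames(cnt), stringsAsFactors = FALSE),
              as.data.frame(cnt))
  .write_tsv(df, path)
  cd <- as.data.frame(SummarizedExperiment::colData(pb))
  .write_tsv(cbind(data.frame(sample_id = colnames(pb)), cd),
             paste0(path, ".meta.tsv"))
  invisible(path)
}

#' @rdname writePseudobulk
#' @export
readPseudobulk <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- .read_tsv(paste0(path, ".meta.tsv"),
                    c("sample_id", "patient", "tissue"), "pseudobulk meta")
  cnt <- t(as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE]))
  colnames(cnt) <- df$sample_id
  storage.mode(cnt) <- "integer"
  meta <- meta[match(df$sample_id, meta$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(meta[, setdiff(names(meta), "sample_id"),
                                  drop = FALSE], row.names = df$sample_id)
  SummarizedExperiment::SummarizedExperiment(assays = list(counts = cnt),
                                             colData = cd)
}

#' Write and read DEG tables
#'
#' @param table DEG table from [pairedDE()]/[filterDEGs()].
#' @param path file path.
#' @return `readDEGTable()` returns the data.frame.
#' @export
writeDEGTable <- function(table, path) {
  .write_tsv(table, path)
  invisible(path)
}

#' @rdname writeDEGTable
#' @export
readDEGTable <- function(path) {
  .read_tsv(path, c("gene_id", "log2fc", "p_value", "direction", "is_deg"),
            "DEG table")
}

#' Export a network to edge/node TSVs and GraphML
#'
#' Writes `<prefix>.edges.tsv`, `<prefix>.nodes.tsv` (node kind, encoding
#' link, stage, plus any annotation columns such as expression direction or a
#' seed-set membership flag) and `<prefix>.graphml` for use in external
#' viewers. Layout is left to the viewer.
#'
#' @param net a [GeneNetwork-class].
#' @param prefix output path prefix.
#' @param seed_set optional seed gene ids; adds an `in_seed_set` node flag.
#' @return The prefix, invisibly.
#' @export
exportNetwork <- function(net, prefix, seed_set = NULL) {
  stopifnot(is(net, "GeneNetwork"))
  nd <- netNodes(net)
  nd$stage <- netStage(net)
  if (!is.null(seed_set)) {
    gene_of <- ifelse(nd$kind == "gene", nd$node_id, nd$encodes)
    nd$in_seed_set <- gene_of %in% seed_set
  }
  .write_tsv(netEdges(net), paste0(prefix, ".edges.tsv"))
  .write_tsv(nd, paste0(prefix, ".nodes.tsv"))
  vert <- nd
  vert$encodes[is.na(vert$encodes)] <- ""
  if (nrow(vert) > 0) {
    g <- igraph::graph_from_data_frame(netEdges(net), directed = TRUE,
                                       vertices = vert)
    igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  }
  invisible(prefix)
}
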