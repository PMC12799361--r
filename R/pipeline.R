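# End-to-end orchestration: preprocess -> paired DE -> stage-1 seed network
# -> candidate regulators -> specificity test -> final network -> census,
# hubs, regulation subnetworks -> gene-age enrichment, with a JSON manifest
# of the counts at every stage.

#' Pipeline configuration
#'
#' Bundles all stage thresholds. Defaults are the reported analysis settings:
#' cells with fewer than 100 detected genes and genes detected in fewer than
#' 3 cells are dropped; DEGs require `p < 0.05` and `|log2FC| > 0.5`;
#' candidate regulators are significant at Bonferroni-adjusted `p < 0.05`;
#' hubs exceed the empirical 95 % connectivity quantile; age intervals are
#' flagged at unadjusted `p < 0.05`.
#'
#' @param min_genes_per_cell,min_cells_per_gene cell/gene QC thresholds.
#' @param target_sum normalisation target (`NULL` = median per-cell total).
#' @param min_patients minimum complete patient pairs for the DE stage.
#' @param pseudocount CPM pseudocount of the DE stage.
#' @param p_thresh,lfc_thresh DEG thresholds.
#' @param specificity_alpha familywise level of the regulator specificity
#'   test.
#' @param hub_alpha tail probability of the hub quantile.
#' @param age_alpha significance threshold of the age enrichment.
#' @param M gene-universe size for the specificity test (`NULL` = distinct
#'   genes in the knowledge graph).
#' @param de_engine `"ttest"` or `"deseq2"`.
#' @param rng_seed seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `PipelineConfig`. Serialises losslessly through
#'   JSON (`jsonlite`).
#' @export
pipelineConfig <- function(min_genes_per_cell = 100, min_cells_per_gene = 3,
                           target_sum = NULL, min_patients = 3,
                           pseudocount = 0.5, p_thresh = 0.05,
                           lfc_thresh = 0.5, specificity_alpha = 0.05,
                           hub_alpha = 0.05, age_alpha = 0.05, M = NULL,
                           de_engine = c("ttest", "deseq2"), rng_seed = 1) {
  cfg <- list(min_genes_per_cell = min_genes_per_cell,
              min_cells_per_gene = min_cells_per_gene,
              target_sum = target_sum, min_patients = min_patients,
              pseudocount = pseudocount, p_thresh = p_thresh,
              lfc_thresh = lfc_thresh, specificity_alpha = specificity_alpha,
              hub_alpha = hub_alpha, age_alpha = age_alpha, M = M,
              de_engine = match.arg(de_engine),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$p_thresh > 0, cfg$p_thresh <= 1,
            cfg$lfc_thresh >= 0, cfg$hub_alpha > 0, cfg$hub_alpha < 1,
            cfg$specificity_alpha > 0, cfg$specificity_alpha <= 1)
  structure(cfg, class = "PipelineConfig")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config a `PipelineConfig`.
#' @param path JSON file path.
#' @return `readPipelineConfig()` returns the restored `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  lst <- unclass(config)
  lst <- lst[!vapply(lst, is.null, logical(1))]  # NULL = resolve at run time
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full seeded-network pipeline
#'
#' Executes preprocessing, paired differential expression, two-stage network
#' reconstruction, the regulator specificity test, edge census, hub
#' detection, direction-filtered regulation subnetworks and (when an age
#' table is supplied) phylostratigraphic enrichment. Any stage failure aborts
#' with the stage name and cause.
#'
#' @param counts a genes x cells counts bundle
#'   ([SingleCellExperiment][SingleCellExperiment::SingleCellExperiment] with
#'   `patient` and `tissue` in colData).
#' @param kg a [KnowledgeGraph-class].
#' @param seed_set character vector of seed gene ids.
#' @param markers character vector of marker gene ids for hepatocyte gating.
#' @param ages optional gene-age data.frame (see [ageEnrichment()]).
#' @param cluster_labels optional per-cell cluster labels for the gating.
#' @param config a [pipelineConfig()].
#' @param out_dir optional output directory; when given, every stage table,
#'   the networks (TSV + GraphML), the resolved configuration and the JSON
#'   manifest are written there.
#' @return A manifest list: per-stage counts (cells/genes kept, DEG summary,
#'   seed-network size, candidate and significant-regulator counts, edge
#'   censuses, hubs, flagged age intervals) plus a `results` element holding
#'   the full objects (DEG table, networks, association results, hub report,
#'   age enrichment).
#' @export
runPipeline <- function(counts, kg, seed_set, markers, ages = NULL,
                        cluster_labels = NULL, config = pipelineConfig(),
                        out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  flt <- .stage("filter", filterCellsGenes(counts,
                                           config$min_genes_per_cell,
                                           config$min_cells_per_gene))
  flt <- .stage("normalize", normalizeLog1p(flt, config$target_sum))
  hep <- .stage("select_hepatocytes",
                selectHepatocytes(flt, markers,
                                  cluster_labels = cluster_labels))
  pb <- .stage("pseudobulk", makePseudobulk(flt, hep))
  degs <- .stage("diffexpr",
                 filterDEGs(pairedDE(pb, min_patients = config$min_patients,
                                     pseudocount = config$pseudocount,
                                     engine = config$de_engine),
                            p_thresh = config$p_thresh,
                            lfc_thresh = config$lfc_thresh))
  deg_summary <- summarizeDEGs(degs)
  net1 <- .stage("seed_network", seedNetwork(degs, seed_set, kg))
  cand <- .stage("candidates", findCandidateRegulators(degs, net1, kg))
  assoc <- .stage("specificity",
                  specificityTest(cand, net1, kg, M = config$M,
                                  alpha = config$specificity_alpha))
  sig <- assoc$protein_id[assoc$significant]
  net2 <- .stage("final_network", assembleFinalNetwork(net1, sig, kg))
  census1 <- edgeCensus(net1)
  census2 <- edgeCensus(net2)
  hubs <- .stage("hubs", detectHubs(nodeConnectivity(net2),
                                    alpha = config$hub_alpha))
  sub_up <- .stage("subnet_up",
                   regulationSubnetwork(net2, "upregulation", degs))
  sub_down <- .stage("subnet_down",
                     regulationSubnetwork(net2, "downregulation", degs))
  age_res <- NULL
  if (!is.null(ages)) {
    net_genes <- union(geneIds(net2),
                       netNodes(net2)$encodes[netNodes(net2)$kind == "protein"])
    age_res <- .stage("phylostrat",
                      ageEnrichment(net_genes, ages,
                                    universe = geneIds(kg),
                                    alpha = config$age_alpha))
  }
  manifest <- list(
    config = unclass(config),
    cells_in = ncol(counts), genes_in = nrow(counts),
    cells_kept = ncol(flt), genes_kept = nrow(flt),
    hepatocyte_cells = length(hep),
    pseudobulk_samples = ncol(pb),
    degs = deg_summary,
    seed_set_size = length(unique(seed_set)),
    seed_deg_genes = length(geneIds(net1)),
    stage1_nodes = nrow(netNodes(net1)),
    stage1_edges = as.list(census1),
    n_candidates = nrow(assoc),
    n_significant = length(sig),
    significant_regulators = sig,
    stage2_nodes = nrow(netNodes(net2)),
    stage2_edges = as.list(census2),
    hub_critical_value = hubs$critical_value,
    hubs = hubs$hubs,
    subnet_up = list(nodes = nrow(netNodes(sub_up)),
                     edges = nrow(netEdges(sub_up))),
    subnet_down = list(nodes = nrow(netNodes(sub_down)),
                       edges = nrow(netEdges(sub_down))),
    flagged_age_intervals = if (is.null(age_res)) integer(0) else
      age_res$interval_index[age_res$significant])
  results <- list(degs = degs, pseudobulk = pb, stage1 = net1,
                  candidates = cand, association = assoc, stage2 = net2,
                  hub_report = hubs, subnet_up = sub_up,
                  subnet_down = sub_down, age_enrichment = age_res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writePseudobulk(pb, file.path(out_dir, "pseudobulk.tsv"))
    writeDEGTable(degs, file.path(out_dir, "deg_table.tsv"))
    exportNetwork(net1, file.path(out_dir, "network_stage1"), seed_set)
    exportNetwork(net2, file.path(out_dir, "network_stage2"), seed_set)
    exportNetwork(sub_up, file.path(out_dir, "subnet_upregulation"), seed_set)
    exportNetwork(sub_down, file.path(out_dir, "subnet_downregulation"),
                  seed_set)
    .write_tsv(assoc, file.path(out_dir, "specificity.tsv"))
    .write_tsv(nodeConnectivity(net2), file.path(out_dir, "connectivity.tsv"))
    if (!is.null(age_res))
      .write_tsv(age_res, file.path(out_dir, "age_enrichment.tsv"))
    writePipelineConfig(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  c(manifest, list(results = results))
}
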