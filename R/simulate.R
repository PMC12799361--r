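# Synthetic-data generators: negative-binomial paired single-cell counts with
# planted fold-changes and marker-high hepatocyte-like cells, a typed
# knowledge graph with planted specific regulators, and a gene-age table with
# planted over-represented strata. All outputs are fully determined by the
# configuration's rng_seed.

#' SimConfig class
#'
#' Configuration of the synthetic-data generators. Defaults describe the
#' emulated study: 8 patients with paired tumor/normal samples, a
#' 2,000-gene panel with 6 hepatocyte marker genes, 60 % hepatocyte-like
#' cells, 50 planted differentially expressed genes at |log2FC| = 2, a
#' 100-gene seed set of which 40 are planted DEGs, 5 planted regulator
#' proteins carrying 10 edges each into the seed network over a background
#' edge probability of 0.005, and 20 gene-age intervals with 2 enriched
#' strata at odds ratio 5.
#'
#' @slot n_patients number of patients (each contributes a tumor and a normal
#'   sample).
#' @slot n_cells_per_sample cells per (patient, tissue) sample.
#' @slot n_genes number of genes.
#' @slot n_marker_genes number of hepatocyte marker genes (the first
#'   `n_marker_genes` gene ids, elevated in hepatocyte-like cells of both
#'   tissues).
#' @slot frac_hepatocyte_cells fraction of hepatocyte-like cells per sample,
#'   in (0, 1].
#' @slot n_planted_degs number of planted DEGs (half up, half down).
#' @slot planted_log2fc magnitude of the planted log2 fold-change, applied in
#'   tumor hepatocyte-like cells only.
#' @slot nb_mean baseline negative-binomial mean per cell and gene.
#' @slot nb_dispersion shared NB dispersion alpha (variance = mu + alpha
#'   mu^2).
#' @slot marker_log2fc log2 elevation of marker genes in hepatocyte-like
#'   cells.
#' @slot patient_sd standard deviation of the per-patient log-mean offset
#'   shared by a patient's tumor and normal samples.
#' @slot seed_set_size size of the seed gene set.
#' @slot seed_deg_overlap number of planted DEGs included in the seed set
#'   (used by [simulateStudy()]).
#' @slot n_planted_regulators number of planted regulator proteins.
#' @slot regulator_edges_to_network edges each planted regulator sends into
#'   the seed set.
#' @slot background_edge_prob per (protein, gene) background edge
#'   probability.
#' @slot n_age_intervals number of gene-age strata.
#' @slot enriched_intervals indices of strata over-represented among network
#'   genes.
#' @slot age_odds_ratio odds ratio of the planted age enrichment.
#' @slot rng_seed integer seed that fully determines all generator outputs.
#' @export
setClass("SimConfig",
         slots = c(n_patients = "integer", n_cells_per_sample = "integer",
                   n_genes = "integer", n_marker_genes = "integer",
                   frac_hepatocyte_cells = "numeric",
                   n_planted_degs = "integer", planted_log2fc = "numeric",
                   nb_mean = "numeric", nb_dispersion = "numeric",
                   marker_log2fc = "numeric", patient_sd = "numeric",
                   seed_set_size = "integer", seed_deg_overlap = "integer",
                   n_planted_regulators = "integer",
                   regulator_edges_to_network = "integer",
                   background_edge_prob = "numeric",
                   n_age_intervals = "integer",
                   enriched_intervals = "integer",
                   age_odds_ratio = "numeric", rng_seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  pos <- c(n_patients = object@n_patients,
           n_cells_per_sample = object@n_cells_per_sample,
           n_genes = object@n_genes, nb_mean = object@nb_mean,
           nb_dispersion = object@nb_dispersion,
           n_age_intervals = object@n_age_intervals)
  if (any(pos <= 0)) msgs <- c(msgs, "counts and NB parameters must be positive")
  if (object@frac_hepatocyte_cells <= 0 || object@frac_hepatocyte_cells > 1)
    msgs <- c(msgs, "frac_hepatocyte_cells must be in (0, 1]")
  if (object@background_edge_prob < 0 || object@background_edge_prob > 1)
    msgs <- c(msgs, "background_edge_prob must be in [0, 1]")
  if (object@n_marker_genes > object@n_genes)
    msgs <- c(msgs, "n_marker_genes exceeds n_genes")
  if (object@n_planted_degs > object@n_genes - object@n_marker_genes)
    msgs <- c(msgs, "n_planted_degs exceeds the number of non-marker genes")
  if (object@seed_set_size > object@n_genes)
    msgs <- c(msgs, "seed_set_size exceeds n_genes")
  if (object@seed_deg_overlap > min(object@seed_set_size, object@n_planted_degs))
    msgs <- c(msgs, "seed_deg_overlap exceeds seed_set_size or n_planted_degs")
  if (object@regulator_edges_to_network > object@seed_set_size)
    msgs <- c(msgs, "regulator_edges_to_network exceeds seed_set_size")
  if (length(object@enriched_intervals) &&
      (any(object@enriched_intervals < 1) ||
       any(object@enriched_intervals > object@n_age_intervals)))
    msgs <- c(msgs, "enriched_intervals out of range")
  if (object@age_odds_ratio <= 0)
    msgs <- c(msgs, "age_odds_ratio must be positive")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Create a synthetic-data configuration
#'
#' @param n_patients,n_cells_per_sample,n_genes,n_marker_genes,frac_hepatocyte_cells,n_planted_degs,planted_log2fc,nb_mean,nb_dispersion,marker_log2fc,patient_sd,seed_set_size,seed_deg_overlap,n_planted_regulators,regulator_edges_to_network,background_edge_prob,n_age_intervals,enriched_intervals,age_odds_ratio,rng_seed
#'   see [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(n_genes = 200, n_planted_degs = 10, rng_seed = 7)
simConfig <- function(n_patients = 8, n_cells_per_sample = 200,
                      n_genes = 2000, n_marker_genes = 6,
                      frac_hepatocyte_cells = 0.6, n_planted_degs = 50,
                      planted_log2fc = 2, nb_mean = 0.5, nb_dispersion = 0.5,
                      marker_log2fc = 5, patient_sd = 0.3,
                      seed_set_size = 100, seed_deg_overlap = 40,
                      n_planted_regulators = 5,
                      regulator_edges_to_network = 10,
                      background_edge_prob = 0.005, n_age_intervals = 20,
                      enriched_intervals = c(3L, 7L), age_odds_ratio = 5,
                      rng_seed = 1) {
  new("SimConfig",
      n_patients = as.integer(n_patients),
      n_cells_per_sample = as.integer(n_cells_per_sample),
      n_genes = as.integer(n_genes),
      n_marker_genes = as.integer(n_marker_genes),
      frac_hepatocyte_cells = frac_hepatocyte_cells,
      n_planted_degs = as.integer(n_planted_degs),
      planted_log2fc = planted_log2fc,
      nb_mean = nb_mean, nb_dispersion = nb_dispersion,
      marker_log2fc = marker_log2fc, patient_sd = patient_sd,
      seed_set_size = as.integer(seed_set_size),
      seed_deg_overlap = as.integer(seed_deg_overlap),
      n_planted_regulators = as.integer(n_planted_regulators),
      regulator_edges_to_network = as.integer(regulator_edges_to_network),
      background_edge_prob = background_edge_prob,
      n_age_intervals = as.integer(n_age_intervals),
      enriched_intervals = as.integer(enriched_intervals),
      age_odds_ratio = age_odds_ratio,
      rng_seed = as.integer(rng_seed))
}

.geneIds <- function(config) sprintf("g%05d", seq_len(config@n_genes))
.proteinOf <- function(gene) {
  # paste0(character(0), "_prot") would recycle to "_prot"
  if (!length(gene)) return(character(0))
  paste0(gene, "_prot")
}

# Distinct RNG streams per generator so that the same rng_seed drives all
# three without re-using draws (offsets keep derived seeds well below 2^31).
.SEED_OFF_KG <- 1000003L
.SEED_OFF_AGE <- 2000003L
.SEED_OFF_STUDY <- 3000003L

#' Simulate a paired single-cell counts bundle with planted truth
#'
#' Draws negative-binomial counts for `n_patients` paired tumor/normal
#' samples. Gene baselines vary log-normally around `nb_mean`; tumor and
#' normal samples of a patient share a log-mean offset (SD `patient_sd`).
#' Marker genes (the first `n_marker_genes` ids) are elevated by
#' `marker_log2fc` in hepatocyte-like cells of both tissues; planted DEGs are
#' shifted by +/- `planted_log2fc` in tumor hepatocyte-like cells only.
#'
#' @param config a [SimConfig-class].
#' @return list with `counts` (a
#'   [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment] of
#'   genes x cells with `patient` and `tissue` in its colData) and `truth`
#'   (list: `deg` data.frame of planted gene_id/log2fc, `hepatocyte_cell_ids`,
#'   `marker_ids`).
#' @export
simulateCounts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@rng_seed)
  G <- config@n_genes
  genes <- .geneIds(config)
  patients <- sprintf("p%02d", seq_len(config@n_patients))
  tissues <- c("normal", "tumor")
  ncell <- config@n_cells_per_sample
  n_hep <- max(1L, round(config@frac_hepatocyte_cells * ncell))

  meta <- expand.grid(idx = seq_len(ncell), tissue = tissues,
                      patient = patients, stringsAsFactors = FALSE)
  meta$is_hep <- meta$idx <= n_hep
  C <- nrow(meta)
  meta$cell_id <- sprintf("%s_%s_c%04d", meta$patient, meta$tissue, meta$idx)

  base_lmu <- log(config@nb_mean) + rnorm(G, 0, 1)  # realistic spread of gene means
  pat_off <- setNames(rnorm(config@n_patients, 0, config@patient_sd), patients)

  markers <- genes[seq_len(config@n_marker_genes)]
  deg_pool <- genes[(config@n_marker_genes + 1L):G]
  deg_genes <- sort(sample(deg_pool, config@n_planted_degs))
  n_up <- ceiling(config@n_planted_degs / 2)
  deg_lfc <- rep(c(config@planted_log2fc, -config@planted_log2fc),
                 c(n_up, config@n_planted_degs - n_up))

  lmu <- outer(base_lmu, unname(pat_off[meta$patient]), "+")
  hep <- meta$is_hep
  tum_hep <- hep & meta$tissue == "tumor"
  lmu[match(markers, genes), hep] <-
    lmu[match(markers, genes), hep] + config@marker_log2fc * log(2)
  if (config@n_planted_degs > 0 && any(tum_hep)) {
    lmu[match(deg_genes, genes), tum_hep] <-
      lmu[match(deg_genes, genes), tum_hep] + deg_lfc * log(2)
  }
  counts <- matrix(rnbinom(G * C, mu = exp(lmu),
                           size = 1 / config@nb_dispersion),
                   nrow = G, ncol = C,
                   dimnames = list(genes, meta$cell_id))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(counts, "CsparseMatrix")),
    colData = S4Vectors::DataFrame(patient = meta$patient,
                                   tissue = meta$tissue,
                                   row.names = meta$cell_id))
  truth <- list(deg = data.frame(gene_id = deg_genes, log2fc = deg_lfc,
                                 stringsAsFactors = FALSE),
                hepatocyte_cell_ids = meta$cell_id[hep],
                marker_ids = markers)
  list(counts = sce, truth = truth)
}

#' Simulate a typed knowledge graph with planted specific regulators
#'
#' Every gene gets exactly one protein product node. Planted regulator
#' proteins (chosen outside the seed set) each send
#' `regulator_edges_to_network` edges into distinct seed-set genes; all
#' proteins additionally carry background edges at `background_edge_prob` per
#' (protein, gene) pair (for regulators, background targets exclude the seed
#' set so their network linkage is exactly the planted one). Edge types are
#' drawn uniformly from the four relationship types; `interaction` edges
#' target the partner gene's protein node, the expression types target the
#' gene node directly. A protein never targets its own gene.
#'
#' @param config a [SimConfig-class].
#' @param genes character vector of gene ids.
#' @param seed_set character vector of seed gene ids (subset of `genes`).
#' @param regulator_genes optional gene ids (disjoint from `seed_set`) whose
#'   proteins are the planted regulators; sampled from the non-seed genes
#'   when `NULL`.
#' @param target_pool genes the planted regulator edges are drawn into
#'   (default: the whole `seed_set`; [simulateStudy()] narrows this to the
#'   seed genes that are also planted DEGs, i.e. the recoverable stage-1
#'   network).
#' @return list with `kg` (a [KnowledgeGraph-class]) and `truth` (list:
#'   `regulator_ids` protein ids, `regulator_genes`).
#' @export
simulateKnowledgeGraph <- function(config, genes, seed_set,
                                   regulator_genes = NULL,
                                   target_pool = seed_set) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (!all(seed_set %in% genes)) stop("seed_set must be a subset of genes")
  if (!all(target_pool %in% seed_set))
    stop("target_pool must be a subset of seed_set")
  if (config@regulator_edges_to_network > length(target_pool))
    stop("regulator_edges_to_network exceeds the planted target pool")
  set.seed(config@rng_seed + .SEED_OFF_KG)
  G <- length(genes)
  prots <- .proteinOf(genes)
  if (is.null(regulator_genes)) {
    pool <- setdiff(genes, seed_set)
    if (length(pool) < config@n_planted_regulators)
      stop("not enough non-seed genes to plant regulators")
    regulator_genes <- sort(sample(pool, config@n_planted_regulators))
  } else {
    if (any(regulator_genes %in% seed_set) ||
        !all(regulator_genes %in% genes))
      stop("regulator_genes must be non-seed genes")
    regulator_genes <- sort(regulator_genes)
  }
  reg_prots <- .proteinOf(regulator_genes)

  mkEdges <- function(src_prot, tgt_gene) {
    type <- sample(edgeTypes(), length(tgt_gene), replace = TRUE)
    target <- ifelse(type == "interaction", .proteinOf(tgt_gene), tgt_gene)
    data.frame(source = src_prot, target = target, type = type,
               stringsAsFactors = FALSE)
  }

  planted <- do.call(rbind, lapply(reg_prots, function(pp) {
    mkEdges(pp, sample(target_pool, config@regulator_edges_to_network))
  }))

  # Background: Bernoulli(background_edge_prob) per (protein, gene) pair,
  # drawn by sampling pair indices without replacement; own-gene pairs and
  # regulator-to-seed pairs are excluded.
  bg <- NULL
  if (config@background_edge_prob > 0) {
    n_bg <- rbinom(1, G * G, config@background_edge_prob)
    if (n_bg > 0) {
      idx <- sample.int(G * G, n_bg)
      pi <- ((idx - 1L) %% G) + 1L         # protein index
      gi <- ((idx - 1L) %/% G) + 1L        # target gene index
      keep <- pi != gi
      src_gene <- genes[pi[keep]]
      tgt <- genes[gi[keep]]
      drop <- src_gene %in% regulator_genes & tgt %in% seed_set
      if (any(!drop))
        bg <- mkEdges(.proteinOf(src_gene[!drop]), tgt[!drop])
    }
  }
  edges <- rbind(planted, bg)
  nodes <- rbind(
    data.frame(node_id = genes, kind = "gene", encodes = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(node_id = prots, kind = "protein", encodes = genes,
               stringsAsFactors = FALSE))
  kg <- KnowledgeGraph(nodes, edges)
  list(kg = kg,
       truth = list(regulator_ids = reg_prots,
                    regulator_genes = regulator_genes))
}

#' Simulate a gene-age table with planted enriched strata
#'
#' Assigns every gene to one of `n_age_intervals` evolutionary-age strata
#' (uniformly for background genes); genes in `network_genes` are oversampled
#' into the `enriched_intervals` at `age_odds_ratio`.
#'
#' @param config a [SimConfig-class].
#' @param genes character vector of gene ids (the universe).
#' @param network_genes character vector (subset of `genes`) receiving the
#'   planted enrichment.
#' @return list with `ages` (data.frame `gene_id`, `interval_index`,
#'   `interval_label` with age ranges in million years) and `truth` (list:
#'   `enriched_interval_ids`).
#' @export
simulateAgeTable <- function(config, genes, network_genes = character(0)) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (!all(network_genes %in% genes))
    stop("network_genes must be a subset of genes")
  set.seed(config@rng_seed + .SEED_OFF_AGE)
  K <- config@n_age_intervals
  breaks <- round(seq(0, 1500, length.out = K + 1))
  labels <- sprintf("%d-%d My", breaks[-(K + 1)], breaks[-1])
  w_net <- rep(1, K)
  w_net[config@enriched_intervals] <- config@age_odds_ratio
  is_net <- genes %in% network_genes
  iv <- integer(length(genes))
  if (any(!is_net)) iv[!is_net] <- sample.int(K, sum(!is_net), replace = TRUE)
  if (any(is_net)) iv[is_net] <- sample.int(K, sum(is_net), replace = TRUE,
                                            prob = w_net / sum(w_net))
  ages <- data.frame(gene_id = genes, interval_index = iv,
                     interval_label = labels[iv], stringsAsFactors = FALSE)
  enriched <- if (config@age_odds_ratio != 1) config@enriched_intervals
              else integer(0)
  list(ages = ages, truth = list(enriched_interval_ids = enriched))
}

#' Simulate a coherent full study
#'
#' Couples the three generators so that the planted structures line up the
#' way the pipeline expects: `seed_deg_overlap` of the planted DEGs are put
#' into the seed set (they form the recoverable seed network), the planted
#' regulators are chosen among planted DEG genes *outside* the seed set (so
#' their proteins qualify as candidates), and the age enrichment is planted
#' on the genes expected to make up the final network (seed DEGs plus
#' regulator genes).
#'
#' @param config a [SimConfig-class].
#' @return list with `counts` (SingleCellExperiment), `kg`
#'   ([KnowledgeGraph-class]), `seed_sets` (named list of gene-id vectors, GMT
#'   style), `ages` (data.frame), `markers` (marker gene ids) and `truth`
#'   (merged planted truth across generators).
#' @export
#' @examples
#' \donttest{
#' sim <- simulateStudy(simConfig(n_genes = 400, n_cells_per_sample = 50,
#'                                seed_set_size = 40, seed_deg_overlap = 20,
#'                                rng_seed = 3))
#' }
simulateStudy <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@n_planted_regulators >
      config@n_planted_degs - config@seed_deg_overlap)
    stop("need n_planted_regulators planted DEGs outside the seed set; ",
         "increase n_planted_degs or decrease seed_deg_overlap")
  cs <- simulateCounts(config)
  genes <- rownames(cs$counts)
  set.seed(config@rng_seed + .SEED_OFF_STUDY)
  deg_genes <- cs$truth$deg$gene_id
  seed_deg <- sort(sample(deg_genes, config@seed_deg_overlap))
  non_deg_pool <- setdiff(genes, c(deg_genes, cs$truth$marker_ids))
  seed_rest <- sort(sample(non_deg_pool,
                           config@seed_set_size - config@seed_deg_overlap))
  seed_set <- sort(c(seed_deg, seed_rest))
  regulator_genes <- sort(sample(setdiff(deg_genes, seed_deg),
                                 config@n_planted_regulators))
  kgres <- simulateKnowledgeGraph(config, genes, seed_set, regulator_genes,
                                  target_pool = seed_deg)
  ageres <- simulateAgeTable(config, genes,
                             network_genes = union(seed_deg, regulator_genes))
  truth <- c(cs$truth, kgres$truth, ageres$truth,
             list(seed_deg_genes = seed_deg))
  list(counts = cs$counts, kg = kgres$kg,
       seed_sets = list(seed = seed_set), ages = ageres$ages,
       markers = cs$truth$marker_ids, truth = truth)
}
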