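test_that("seed network pairs DEG seed genes with their proteins", {
  kg <- tinyKG()
  genes <- paste0("g", LETTERS[1:5])
  deg <- degTable(genes, deg_ids = c("gA", "gB"))
  net <- seedNetwork(deg, c("gA", "gB", "gD"), kg)
  expect_setequal(netNodes(net)$node_id, c("gA", "gB", "gA_prot", "gB_prot"))
  expect_equal(netStage(net), "stage1")
  # gene and protein node counts match in any stage-1 network
  expect_equal(length(geneIds(net)), length(proteinIds(net)))
  # induced edges only: both endpoints inside
  ed <- netEdges(net)
  expect_true(all(c(ed$source, ed$target) %in% netNodes(net)$node_id))
  expect_setequal(paste(ed$source, ed$target),
                  c("gA_prot gB", "gB_prot gA"))
  # no DEG among the seed genes: empty network plus warning
  expect_warning(net0 <- seedNetwork(degTable(genes, deg_ids = character(0)),
                                     c("gD", "gE"), kg), "empty")
  expect_equal(nrow(netNodes(net0)), 0L)
})

test_that("synthetic seed network has 2x the DEG-overlap node count", {
  cfg <- simConfig(n_genes = 1000, seed_set_size = 100, seed_deg_overlap = 40,
                   n_planted_degs = 50, n_cells_per_sample = 30,
                   n_patients = 3, rng_seed = 19)
  sim <- simulateStudy(cfg)
  deg <- degTable(rownames(sim$counts), deg_ids = sim$truth$deg$gene_id)
  net <- seedNetwork(deg, sim$seed_sets$seed, sim$kg)
  expect_equal(nrow(netNodes(net)), 80L)  # 40 genes + 40 proteins
})

test_that("candidate discovery excludes network proteins and off-network edges", {
  kg <- tinyKG()
  genes <- paste0("g", LETTERS[1:5])
  deg <- degTable(genes)
  net <- seedNetwork(deg, c("gA", "gE"), kg)
  cand <- findCandidateRegulators(deg, net, kg)
  # gA_prot/gE_prot are stage-1 members; gB, gC (via interaction with
  # gA_prot), gD qualify
  expect_setequal(cand$protein_id, c("gB_prot", "gC_prot", "gD_prot"))
  expect_true(all(vapply(cand$targets, function(t)
    all(t %in% geneIds(net)), logical(1))))
  # a protein with edges only to non-network genes is excluded
  net2 <- seedNetwork(deg, c("gB", "gC"), kg)
  cand2 <- findCandidateRegulators(deg, net2, kg)
  expect_false("gD_prot" %in% cand2$protein_id)  # gD only regulates gE
  expect_true("gA_prot" %in% cand2$protein_id)
})

test_that("with zero background the candidates are exactly the planted regulators", {
  cfg <- simConfig(n_genes = 400, seed_set_size = 50, seed_deg_overlap = 20,
                   n_planted_degs = 30, n_planted_regulators = 4,
                   regulator_edges_to_network = 8,
                   background_edge_prob = 0, rng_seed = 23)
  genes <- sprintf("g%05d", 1:400)
  seed_set <- genes[1:50]
  kgres <- simulateKnowledgeGraph(cfg, genes, seed_set)
  deg <- degTable(genes)
  net <- seedNetwork(deg, seed_set, kgres$kg)
  cand <- findCandidateRegulators(deg, net, kgres$kg)
  expect_setequal(cand$protein_id, kgres$truth$regulator_ids)
})

test_that("final-network assembly adds exactly the significant proteins", {
  kg <- tinyKG()
  genes <- paste0("g", LETTERS[1:5])
  deg <- degTable(genes, deg_ids = c("gA", "gE"))
  net1 <- seedNetwork(deg, c("gA", "gE"), kg)
  # empty significant set: final network equals stage 1 (except the tag)
  net2a <- assembleFinalNetwork(net1, character(0), kg)
  expect_identical(netNodes(net2a)[, c("node_id", "kind", "encodes")],
                   netNodes(net1)[, c("node_id", "kind", "encodes")])
  expect_identical(netEdges(net2a), netEdges(net1))
  expect_equal(netStage(net2a), "stage2")
  net2b <- assembleFinalNetwork(net1, c("gB_prot", "gD_prot"), kg)
  expect_equal(nrow(netNodes(net2b)), nrow(netNodes(net1)) + 2L)
  expect_gte(nrow(netEdges(net2b)), nrow(netEdges(net1)))
  expect_error(assembleFinalNetwork(net1, "gA_prot", kg), "disjoint")
  expect_error(assembleFinalNetwork(net1, "gA", kg), "protein nodes")
})

test_that("edge census partitions the edge set and grows monotonically", {
  kg <- tinyKG()
  genes <- paste0("g", LETTERS[1:5])
  deg <- degTable(genes)
  net <- seedNetwork(deg, genes, kg)
  cen <- edgeCensus(net)
  expect_equal(unname(cen["total"]), nrow(netEdges(net)))
  expect_equal(sum(cen[edgeTypes()]), unname(cen["total"]))
  expect_true(all(edgeCensus(GeneNetwork(netNodes(net))) == 0L))
  # induced monotonicity stage 1 -> stage 2, per type, across random graphs
  for (rep in 1:50) {
    cfg <- simConfig(n_genes = 120, seed_set_size = 25, seed_deg_overlap = 10,
                     n_planted_degs = 20, n_planted_regulators = 2,
                     regulator_edges_to_network = 5,
                     background_edge_prob = 0.02, rng_seed = 400 + rep)
    gg <- sprintf("g%05d", 1:120)
    kgr <- simulateKnowledgeGraph(cfg, gg, gg[1:25])
    dg <- degTable(gg)
    n1 <- seedNetwork(dg, gg[1:25], kgr$kg)
    cand <- findCandidateRegulators(dg, n1, kgr$kg)
    n2 <- assembleFinalNetwork(n1, cand$protein_id, kgr$kg)
    expect_true(all(edgeCensus(n2) >= edgeCensus(n1)))
  }
})

test_that("regulation subnetworks keep one edge type with expression labels", {
  kg <- tinyKG()
  genes <- paste0("g", LETTERS[1:5])
  deg <- degTable(genes, deg_ids = genes, up_ids = c("gA", "gB"))
  net <- assembleFinalNetwork(seedNetwork(deg, genes, kg), character(0), kg)
  up <- regulationSubnetwork(net, "upregulation", deg)
  down <- regulationSubnetwork(net, "downregulation", deg)
  expect_true(all(netEdges(up)$type == "expression_upregulation"))
  expect_true(all(netEdges(down)$type == "expression_downregulation"))
  # disjoint edge sets, every node has degree >= 1 inside its subnetwork
  key <- function(ed) paste(ed$source, ed$target, ed$type)
  expect_length(intersect(key(netEdges(up)), key(netEdges(down))), 0)
  deg_up <- nodeConnectivity(up)
  expect_true(all(deg_up$connectivity >= 1))
  # node annotation carries the encoding gene's DE direction
  nd <- netNodes(up)
  expect_equal(nd$expression[nd$node_id == "gA_prot"], "up")
  expect_equal(nd$expression[nd$node_id == "gB"], "up")
  expect_error(regulationSubnetwork(net, "sideways", deg))
  # a network without downregulation edges gives an empty subnetwork
  kg2 <- KnowledgeGraph(kgNodes(kg),
                        kgEdges(kg)[kgEdges(kg)$type !=
                                      "expression_downregulation", ])
  net2 <- assembleFinalNetwork(seedNetwork(deg, genes, kg2), character(0), kg2)
  expect_equal(nrow(netEdges(regulationSubnetwork(net2, "downregulation",
                                                  deg))), 0L)
})

test_that("construction is canonical and relabeling-invariant", {
  kg <- tinyKG()
  genes <- paste0("g", LETTERS[1:5])
  deg <- degTable(genes)
  net <- seedNetwork(deg, genes, kg)
  # shuffled input rows give identical objects
  nd <- kgNodes(kg)[sample(nrow(kgNodes(kg))), ]
  ed <- kgEdges(kg)[sample(nrow(kgEdges(kg))), ]
  net_shuf <- seedNetwork(deg, rev(genes), KnowledgeGraph(nd, ed))
  expect_identical(netNodes(net), netNodes(net_shuf))
  expect_identical(netEdges(net), netEdges(net_shuf))
  # bijective relabeling of every id relabels the outputs identically
  relab <- setNames(paste0("x", seq_along(kgNodes(kg)$node_id)),
                    kgNodes(kg)$node_id)
  nd2 <- data.frame(node_id = unname(relab[kgNodes(kg)$node_id]),
                    kind = kgNodes(kg)$kind,
                    encodes = ifelse(is.na(kgNodes(kg)$encodes), NA,
                                     unname(relab[kgNodes(kg)$encodes])))
  ed2 <- data.frame(source = unname(relab[kgEdges(kg)$source]),
                    target = unname(relab[kgEdges(kg)$target]),
                    type = kgEdges(kg)$type)
  deg2 <- deg; deg2$gene_id <- unname(relab[deg$gene_id])
  net2 <- seedNetwork(deg2, unname(relab[genes]), KnowledgeGraph(nd2, ed2))
  expect_setequal(netNodes(net2)$node_id, unname(relab[netNodes(net)$node_id]))
  expect_equal(nrow(netEdges(net2)), nrow(netEdges(net)))
})
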