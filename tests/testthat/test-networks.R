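test_that("DEM network induction builds exactly DEMs plus supported targets", {
  rel <- data.frame(mirna_id = c("m1", "m2", "m3"),
                    gene_id = c("g1", "g1", "g9"),
                    r = c(-0.9, -0.8, -0.7), p = 1e-6, q = 1e-4,
                    conserved = TRUE, n = 77)
  dems <- data.frame(feature_id = c("m1", "m2"), direction = c("up", "down"))
  net <- induce_dem_network(rel, dems, degs = c("g1"))
  expect_setequal(net$nodes$id, c("m1", "m2", "g1"))  # m3 is not a DEM
  expect_equal(nrow(net$edges), 2)
  expect_true(net$nodes$is_deg[net$nodes$id == "g1"])
  expect_equal(net$nodes$direction[net$nodes$id == "m1"], "up")
  # two DEMs sharing one target form a single 3-node component
  comps <- network_components(net)
  expect_length(comps, 1)
  expect_setequal(comps[[1]], c("m1", "m2", "g1"))
  # no DEMs -> empty network
  net0 <- induce_dem_network(rel, dems[0, ])
  expect_equal(nrow(net0$nodes), 0)
  expect_length(network_components(net0), 0)
})

test_that("connected components equal a union-find oracle on random graphs", {
  for (seed in 1:50) {
    net <- random_mixed_network(seed, n_tf = 3, n_mirna = 5, n_gene = 7,
                                p_edge = 0.12)
    got <- network_components(net)
    want <- components_oracle(net$nodes$id, net$edges$from, net$edges$to)
    norm <- function(l) sort(vapply(lapply(l, sort), paste, "", collapse = "|"))
    expect_identical(norm(got), norm(want))
  }
})

test_that("adding an edge between two components merges exactly those two", {
  nodes <- data.frame(id = c("m1", "g1", "m2", "g2"),
                      type = c("miRNA", "gene", "miRNA", "gene"))
  edges <- data.frame(from = c("m1", "m2"), to = c("g1", "g2"),
                      type = "mirna_target")
  net <- regulatory_network(nodes, edges)
  expect_length(network_components(net), 2)
  edges2 <- rbind(edges, data.frame(from = "m1", to = "g2", type = "mirna_target"))
  expect_length(network_components(regulatory_network(nodes, edges2)), 1)
})

test_that("circuit enumeration equals the all-triples brute-force oracle", {
  for (seed in 1:50) {
    net <- random_mixed_network(seed + 100, n_tf = 6, n_mirna = 10, n_gene = 14,
                                p_edge = 0.15)
    got <- enumerate_circuits(net)
    got_keys <- sort(paste(got$circuit_type, got$tf, got$mirna, got$gene,
                           sep = "|"))
    expect_identical(got_keys, circuits_oracle(net))
    if (nrow(got) > 1) expect_true(!is.unsorted(got$combined_p))
  }
})

test_that("single-circuit fixtures produce exactly one circuit of the right type", {
  nodes <- data.frame(id = c("t1", "m1", "g1"), type = c("TF", "miRNA", "gene"))
  edges <- data.frame(from = c("t1", "t1", "m1"), to = c("m1", "g1", "g1"),
                      type = c("tf_mirna", "tf_gene", "mirna_target"),
                      r = c(0.8, 0.7, -0.9), p = c(1e-4, 1e-3, 1e-6), q = 0.01)
  circ <- enumerate_circuits(regulatory_network(nodes, edges))
  expect_equal(nrow(circ), 1)
  expect_equal(circ$circuit_type, "TF_driven")
  # Fisher combination of the three edge p-values
  expect_equal(circ$combined_p,
               pchisq(-2 * sum(log(c(1e-4, 1e-3, 1e-6))), df = 6, lower.tail = FALSE))
  # miRNA-driven variant
  edges2 <- data.frame(from = c("m1", "m1", "t1"), to = c("t1", "g1", "g1"),
                       type = c("mirna_target", "mirna_target", "tf_gene"),
                       r = c(-0.8, -0.7, 0.9), p = c(1e-4, 1e-3, 1e-6), q = 0.01)
  circ2 <- enumerate_circuits(regulatory_network(nodes, edges2))
  expect_equal(circ2$circuit_type, "miRNA_driven")
  # network without TF nodes has no circuits
  net_no_tf <- regulatory_network(
    data.frame(id = c("m1", "g1"), type = c("miRNA", "gene")),
    data.frame(from = "m1", to = "g1", type = "mirna_target"))
  expect_equal(nrow(enumerate_circuits(net_no_tf)), 0)
})

test_that("the mixed network keeps planted TF edges and reduces without TF input", {
  cfg <- cohort_config(seed = 19)
  co <- generate_cohort(cfg)
  pred <- generate_target_predictions(co$truth, cfg)
  tf <- generate_tf_layer(co$truth, cfg)
  mirna_f <- filter_by_mean_signal(co$mirna, 5)
  rel <- support_targets(mirna_f, co$gene, pred, sheet = co$sheet, q_max = 0.01)
  net <- build_mixed_network(mirna_f, co$gene, co$sheet, rel, tf,
                             top_gene_fraction = 0.75, q_max = 0.05)
  expect_true(all(net$edges$type[net$edges$r > 0] != "mirna_target"))
  # planted TF-driven circuits whose miRNA survived filtering are wired up
  circ <- enumerate_circuits(net)
  truth_ci <- co$truth$circuits
  reachable <- truth_ci$mirna %in% rownames(mirna_f)
  found <- paste(truth_ci$circuit_type, truth_ci$tf, truth_ci$mirna,
                 truth_ci$gene) %in%
    paste(circ$circuit_type, circ$tf, circ$mirna, circ$gene)
  expect_true(all(found[reachable]))
  # with no TF interactions the mixed network is purely post-transcriptional
  net0 <- build_mixed_network(mirna_f, co$gene, co$sheet, rel, tf[0, ],
                              top_gene_fraction = 1.0, q_max = 0.05)
  expect_true(all(net0$edges$type == "mirna_target"))
  expect_setequal(paste(net0$edges$from, net0$edges$to),
                  paste(rel$mirna_id[rel$q <= 0.05], rel$gene_id[rel$q <= 0.05]))
  # decoy TF edges are controlled: retained decoy fraction stays near q_max
  decoy_edges <- net$edges$type %in% c("tf_gene", "tf_mirna") &
    !(net$edges$from %in% co$truth$circuit_tfs)
  n_decoy_candidates <- sum(tf$source_label == "decoy")
  expect_lte(sum(decoy_edges), max(3, 0.1 * n_decoy_candidates))
})

test_that("circuit count grows monotonically as q_max is relaxed", {
  cfg <- cohort_config(seed = 29)
  co <- generate_cohort(cfg)
  pred <- generate_target_predictions(co$truth, cfg)
  tf <- generate_tf_layer(co$truth, cfg)
  mirna_f <- filter_by_mean_signal(co$mirna, 5)
  rel <- support_targets(mirna_f, co$gene, pred, sheet = co$sheet, q_max = 0.05)
  counts <- vapply(c(0.001, 0.01, 0.05), function(qm) {
    net <- build_mixed_network(mirna_f, co$gene, co$sheet, rel, tf, q_max = qm)
    nrow(enumerate_circuits(net))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})
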