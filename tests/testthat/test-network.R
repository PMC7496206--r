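profiles_df <- function(...) {
  x <- c(...)
  data.frame(entity = names(x), profile = unname(x),
             stringsAsFactors = FALSE)
}

resolved <- function(mirna, gene, level = 3L) {
  data.frame(mirna = mirna, gene = gene, level = as.integer(level),
             stringsAsFactors = FALSE)
}

test_that("pair_inverse keeps only inverse-profile evidence-backed DE pairs", {
  mp <- profiles_df(m1 = "HD", m2 = "HD", m3 = "FLAT", m4 = "LD")
  gp <- profiles_df(g1 = "HI", g2 = "HD", g3 = "HI", g4 = "LI")
  ev <- resolved(c("m1", "m2", "m3", "m4"), c("g1", "g2", "g3", "g4"))
  high <- pair_inverse(mp, gp, ev, "high")
  # m1->g1: HD vs HI inverse -> edge; m2->g2 not inverse; m3 FLAT;
  # m4 LD has no change at high glucose
  expect_equal(high$mirna, "m1")
  expect_equal(high$mirna_direction, "down")
  expect_equal(high$gene_profile, "HI")
  low <- pair_inverse(mp, gp, ev, "low")
  # at low glucose only the LD/LI pair is active
  expect_equal(low$mirna, "m4")
  expect_equal(low$mirna_direction, "down")
})

test_that("unknown ids in evidence are skipped with a warning", {
  mp <- profiles_df(m1 = "I")
  gp <- profiles_df(g1 = "D")
  ev <- resolved(c("m1", "ghost"), c("g1", "g1"))
  expect_warning(edges <- pair_inverse(mp, gp, ev, "high"), "unknown ids")
  expect_equal(nrow(edges), 1L)
})

test_that("both-comparison types contribute to both condition networks", {
  mp <- profiles_df(m1 = "I")
  gp <- profiles_df(g1 = "D")
  edges <- build_mti_edges(mp, gp, resolved("m1", "g1"))
  expect_equal(nrow(edges), 2L)
  expect_setequal(edges$condition, c("low", "high"))
  # I-type miRNA: down at low glucose, up at high
  expect_equal(edges$mirna_direction[edges$condition == "low"], "down")
  expect_equal(edges$mirna_direction[edges$condition == "high"], "up")
})

test_that("split_networks partitions edges and counts nodes", {
  edges <- rbind(star_edges(2, "mA", "high", "down"),
                 star_edges(1, "mB", "high", "up"),
                 star_edges(3, "mC", "low", "down"))
  nets <- split_networks(edges)
  expect_equal(nets$summary$n_edges,
               c(high_dn = 2L, high_up = 1L, low_dn = 3L, low_up = 0L),
               ignore_attr = TRUE)
  # partition: union is everything, intersections empty
  recombined <- rbind(nets$high_dn, nets$high_up, nets$low_dn, nets$low_up)
  expect_equal(nrow(recombined), nrow(edges))
  expect_equal(nets$summary$n_mirnas[1], 1L)
  expect_equal(nets$summary$n_genes[3], 3L)
})

test_that("hub detection uses a strict degree threshold with ordered ties", {
  star <- star_edges(11)
  expect_equal(hub_mirnas(star, min_targets = 10)$mirna, "mirA")
  expect_equal(nrow(hub_mirnas(star, min_targets = 11)), 0L)
  mixed <- rbind(star_edges(12, "mB"), star_edges(12, "mA"),
                 star_edges(13, "mC"))
  hubs <- hub_mirnas(mixed, min_targets = 10)
  expect_equal(hubs$mirna, c("mC", "mA", "mB"))
  # brute-force degree comparison on a random fixture
  set.seed(31)
  rnd <- data.frame(
    mirna = sample(sprintf("m%02d", 1:8), 200, replace = TRUE),
    gene = sprintf("g%03d", 1:200), condition = "high",
    mirna_direction = "down", level = 3L, mirna_profile = "HD",
    gene_profile = "HI", stringsAsFactors = FALSE)
  hubs <- hub_mirnas(rnd, min_targets = 20)
  brute <- sort(table(rnd$mirna), decreasing = TRUE)
  brute <- brute[brute > 20]
  expect_setequal(hubs$mirna, names(brute))
  expect_equal(stats::setNames(hubs$n_targets, hubs$mirna),
               stats::setNames(as.integer(brute), names(brute))[hubs$mirna])
})

test_that("TF layer keeps only DE TFs regulating DE miRNAs", {
  gp <- profiles_df(tf1 = "HI", tf2 = "FLAT")
  mp <- profiles_df(m1 = "HD", m2 = "FLAT")
  tf_table <- data.frame(
    tf_gene = c("tf1", "tf1", "tf2", "absent"),
    mirna = c("m1", "m2", "m1", "m1"),
    sign = c("repress", "activate", "repress", "repress"),
    stringsAsFactors = FALSE)
  expect_warning(layer <- build_tf_layer(tf_table, gp, mp), "absent")
  expect_equal(nrow(layer), 1L)
  expect_equal(layer$tf_gene, "tf1")
  expect_equal(layer$mirna, "m1")
  expect_equal(layer$sign, "repress")
})

test_that("a planted TF hub's out-degree is recovered", {
  cfg <- simulation_config(n_tfs = 1, tf_links_per_tf = 19, n_decoy_tfs = 0,
                           seed = 37)
  sim <- simulate_study(cfg)
  layer <- build_tf_layer(sim$tf_table, sim$truth$gene_profiles,
                          sim$truth$mirna_profiles)
  deg <- table(layer$tf_gene)
  expect_equal(length(deg), 1L)
  expect_equal(as.integer(deg), 19L)
  expect_setequal(paste(layer$tf_gene, layer$mirna),
                  paste(sim$truth$tf_links$tf_gene,
                        sim$truth$tf_links$mirna))
})

test_that("every produced mti edge satisfies the inverse-type invariant", {
  run <- run_simulated_pipeline(simulation_config(seed = 41,
                                                  noise_log2_sd = 0.1))
  edges <- run$result$edges
  expect_gt(nrow(edges), 0)
  expect_true(all(edges$gene_profile ==
                    inverse_type(edges$mirna_profile)))
  expect_true(all(edges$level %in% 1:3))
})

test_that("network exports round-trip and emit valid formats", {
  tmp <- withr::local_tempdir()
  edges <- rbind(star_edges(5, "mA"), star_edges(3, "mB", "low", "up"))
  tsv <- file.path(tmp, "edges.tsv")
  export_network(edges, tsv, "edge-tsv")
  back <- read_edge_tsv(tsv)
  expect_equal(back[, names(edges)], edges, ignore_attr = TRUE)
  sif <- file.path(tmp, "net.sif")
  export_network(edges, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, 8L)
  expect_true(all(grepl("^\\S+ mti_L3 \\S+$", lines)))
  gml <- file.path(tmp, "net.graphml")
  tf_edges <- data.frame(tf_gene = "tfX", mirna = "mA", sign = "repress",
                         tf_profile = "HI", mirna_profile = "HD",
                         stringsAsFactors = FALSE)
  export_network(edges, gml, "graphml", tf_edges = tf_edges)
  doc <- xml2::read_xml(gml)  # well-formed XML in the graphml namespace
  expect_match(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 9L)
  expect_true("tf_mirna" %in% igraph::E(g)$interaction)
  # empty exports still produce valid files
  empty <- edges[0, ]
  export_network(empty, file.path(tmp, "empty.tsv"), "edge-tsv")
  expect_equal(nrow(read_edge_tsv(file.path(tmp, "empty.tsv"))), 0L)
  export_network(empty, file.path(tmp, "empty.sif"), "sif")
  export_network(empty, file.path(tmp, "empty.graphml"), "graphml")
  expect_error(export_network(edges, tsv, "dot"), "arg")
})
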