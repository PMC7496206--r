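test_that("configuration invariants are enforced", {
  bad_mix <- default_mix <- c(I = 0.2, D = 0.2, M = 0.1, V = 0.1, LD = 0.1,
                              LI = 0.1, HI = 0.1, HD = 0.05, FLAT = 0.05)
  bad_mix[["I"]] <- 0.5  # no longer sums to 1
  expect_error(simulation_config(profile_mix = bad_mix), "sum to 1")
  expect_error(simulation_config(effect_size_log2 = 0.5),
               "strictly exceed")  # below log2(1.5)
  expect_error(simulation_config(noise_log2_sd = -1), ">= 0")
  expect_error(simulation_config(ip_support_prob = 1.5), "\\[0,1\\]")
  expect_error(
    simulation_config(evidence_tier_mix = c(strong = 1, weak = 0.2,
                                            predicted = 0)),
    "sum to 1")
  cfg <- simulation_config(profile_mix = default_mix)
  expect_s3_class(cfg, "glucomir_sim_config")
})

test_that("planted signatures produce exact fold changes without noise", {
  # a type-I entity at moderate 100 with a 2-fold effect sits at 50/100/200
  cfg <- simulation_config(
    n_genes = 8,
    profile_mix = c(I = 1, D = 0, M = 0, V = 0, LD = 0, LI = 0, HI = 0,
                    HD = 0, FLAT = 0),
    base_abundance_log_sd = 0, base_abundance_log_mean = log2(100),
    min_moderate_abundance = 100, effect_size_log2 = 1, seed = 3)
  gen <- generate_expression(cfg, "gene")
  expect_true(all(gen$matrix$moderate == 100))
  expect_true(all(gen$matrix$low == 50))
  expect_true(all(gen$matrix$high == 200))
})

test_that("an all-FLAT study yields zero DE entities downstream", {
  cfg <- simulation_config(
    n_genes = 50, n_mirnas = 10,
    profile_mix = c(I = 0, D = 0, M = 0, V = 0, LD = 0, LI = 0, HI = 0,
                    HD = 0, FLAT = 1),
    n_true_mti = 0, seed = 5)
  gen <- generate_expression(cfg, "gene")
  low <- call_differential(gen$matrix, gene_thresholds(), "low_vs_mod")
  high <- call_differential(gen$matrix, gene_thresholds(), "high_vs_mod")
  expect_true(all(low$verdict == "nc"))
  expect_true(all(high$verdict == "nc"))
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- simulation_config(n_genes = 200, seed = 7)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  c <- simulate_study(simulation_config(n_genes = 200, seed = 8))
  expect_false(identical(a$gene_expr, c$gene_expr))
})

test_that("noiseless classification recovers every planted non-FLAT type", {
  cfg <- simulation_config(n_genes = 300, n_mirnas = 80, seed = 13)
  for (kind in c("gene", "mirna")) {
    th <- if (kind == "gene") gene_thresholds() else mirna_thresholds()
    gen <- generate_expression(cfg, kind)
    classified <- classify_entities(
      call_differential(gen$matrix, th, "low_vs_mod"),
      call_differential(gen$matrix, th, "high_vs_mod"))
    expect_identical(classified$profile, gen$profiles$profile)
  }
})

test_that("true evidence rows always pass and decoys always fail consensus", {
  cfg <- simulation_config(n_true_mti = 40, decoy_rate = 1, seed = 21)
  sim <- simulate_study(cfg)
  merged <- merge_evidence(sim$experimental, sim$predictions)
  accepted <- consensus_accept(merged)
  key <- paste(merged$mirna, merged$gene)
  tm <- sim$truth$true_mtis
  predicted_true <- paste(tm$mirna, tm$gene)[tm$tier == "predicted"]
  is_true <- key %in% paste(tm$mirna, tm$gene)
  # independent re-evaluation of each generated row against the rule
  expect_true(all(accepted[key %in% predicted_true]))
  expect_true(all(!accepted[!is_true]))
  # experimental tiers resolve to their levels regardless of predictions
  res <- resolve_evidence(merged)
  lvl <- stats::setNames(res$level, paste(res$mirna, res$gene))
  expect_true(all(lvl[paste(tm$mirna, tm$gene)[tm$tier == "strong"]] == 1L))
  expect_true(all(lvl[paste(tm$mirna, tm$gene)[tm$tier == "weak"]] == 2L))
  # consensus + experimental acceptance recovers exactly the planted set
  expect_setequal(paste(res$mirna, res$gene), paste(tm$mirna, tm$gene))
})

test_that("IP tables place supported entities above and others below the floors", {
  cfg <- simulation_config(ip_support_prob = 0.5, seed = 17)
  sim <- simulate_study(cfg)
  ip <- sim$truth$ip_supported
  expect_true(all(paste(ip$mirna, ip$gene) %in%
                    paste(sim$truth$true_mtis$mirna,
                          sim$truth$true_mtis$gene)))
  gene_vals <- stats::setNames(sim$gene_ip$ip, sim$gene_ip$id)
  mirna_vals <- stats::setNames(sim$mirna_ip$ip, sim$mirna_ip$id)
  expect_true(all(gene_vals[unique(ip$gene)] >= 8))
  expect_true(all(mirna_vals[unique(ip$mirna)] >= 100))
  expect_true(all(gene_vals[setdiff(names(gene_vals), ip$gene)] < 8))
  expect_true(all(mirna_vals[setdiff(names(mirna_vals), ip$mirna)] < 100))
})

test_that("ip_support_prob extremes empty or saturate the planted IP set", {
  none <- simulate_study(simulation_config(ip_support_prob = 0, seed = 2))
  expect_equal(nrow(none$truth$ip_supported), 0L)
  full <- simulate_study(simulation_config(ip_support_prob = 1, seed = 2))
  expect_equal(nrow(full$truth$ip_supported), 50L)
})

test_that("TF tables name planted DE hubs plus FLAT decoys", {
  cfg <- simulation_config(n_tfs = 2, tf_links_per_tf = 4, n_decoy_tfs = 1,
                           seed = 19)
  sim <- simulate_study(cfg)
  gp <- stats::setNames(sim$truth$gene_profiles$profile,
                        sim$truth$gene_profiles$entity)
  links <- sim$truth$tf_links
  expect_true(all(gp[unique(links$tf_gene)] != "FLAT"))
  expect_equal(nrow(links), 8L)
  decoys <- setdiff(unique(sim$tf_table$tf_gene), unique(links$tf_gene))
  expect_true(all(gp[decoys] == "FLAT"))
  expect_true(all(sim$tf_table$tf_gene %in% sim$gene_expr$id))
})

test_that("written simulations round-trip through the pipeline loaders", {
  tmp <- withr::local_tempdir()
  sim <- simulate_study(simulation_config(n_genes = 40, n_mirnas = 15,
                                          n_true_mti = 5, seed = 23))
  paths <- write_simulation(sim, tmp)
  expect_equal(read_expression(paths[["gene_expr"]]), sim$gene_expr,
               tolerance = 1e-12)
  expect_identical(load_experimental(paths[["experimental"]]),
                   sim$experimental)
  pred <- load_predictions(as.list(stats::setNames(
    paths[paste0("predictions_", c("miranda", "pita", "targetscan",
                                   "rnahybrid"))],
    c("miranda", "pita", "targetscan", "rnahybrid"))))
  expect_setequal(paste(pred$mirna, pred$gene, pred$tool),
                  paste(sim$predictions$mirna, sim$predictions$gene,
                        sim$predictions$tool))
  truth_json <- jsonlite::read_json(paths[["truth_profiles"]])
  expect_equal(length(truth_json$gene_profiles), 40L)
})
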