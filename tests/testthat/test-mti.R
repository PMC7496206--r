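test_that("consensus rule accepts and rejects canonical cases", {
  acc <- make_evidence(hits = list(miranda = c(150, -12), pita = c(1, -11),
                                   targetscan = c(0.5, -13)))
  expect_true(consensus_accept(acc))
  two_tools <- make_evidence(hits = list(pita = c(1, -15),
                                         rnahybrid = c(2, -18)))
  expect_false(consensus_accept(two_tools))
  low_miranda <- make_evidence(hits = list(miranda = c(120, -15),
                                           pita = c(1, -12),
                                           rnahybrid = c(2, -14)))
  expect_false(consensus_accept(low_miranda))
  # three tools without miranda satisfy the rule
  no_miranda <- make_evidence(hits = list(pita = c(1, -12),
                                          targetscan = c(0.1, -11),
                                          rnahybrid = c(2, -14)))
  expect_true(consensus_accept(no_miranda))
  expect_false(consensus_accept(no_miranda, require_miranda = TRUE))
  # mfe boundary: -10 passes, anything above fails when it is the only hit
  at_cutoff <- make_evidence(hits = list(pita = c(1, -10),
                                         targetscan = c(0.1, -9),
                                         rnahybrid = c(2, -9)))
  expect_true(consensus_accept(at_cutoff))
  expect_false(consensus_accept(at_cutoff, mfe_all_hits = TRUE))
  all_weak <- make_evidence(hits = list(pita = c(1, -9),
                                        targetscan = c(0.1, -8),
                                        rnahybrid = c(2, -5)))
  expect_false(consensus_accept(all_weak))
})

test_that("consensus matches brute-force enumeration over tool subsets and boundary values", {
  tools <- c("miranda", "pita", "targetscan", "rnahybrid")
  miranda_scores <- c(139, 140, 141)
  mfes <- c(-10.5, -10, -9.5)
  n_cases <- 0
  for (subset_bits in 0:15) {
    chosen <- tools[bitwAnd(subset_bits, c(1L, 2L, 4L, 8L)) > 0]
    if (!length(chosen)) next
    # each chosen tool takes each boundary mfe; miranda each boundary score
    grids <- rep(list(seq_along(mfes)), length(chosen))
    combos <- do.call(expand.grid, grids)
    for (i in seq_len(nrow(combos))) {
      sc_grid <- if ("miranda" %in% chosen) miranda_scores else 0
      for (msc in sc_grid) {
        hits <- list()
        for (j in seq_along(chosen)) {
          tool <- chosen[j]
          score <- if (tool == "miranda") msc else 1
          hits[[tool]] <- c(score, mfes[combos[i, j]])
        }
        ev <- make_evidence(hits = hits)
        expect_identical(consensus_accept(ev), oracle_consensus(hits))
        n_cases <- n_cases + 1
      }
    }
  }
  expect_gte(n_cases, 256)
})

test_that("evidence levels follow strength precedence", {
  strong <- make_evidence(strong = TRUE)
  expect_equal(evidence_level(strong), 1L)
  weak <- make_evidence(weak = TRUE)
  expect_equal(evidence_level(weak), 2L)
  pred <- make_evidence(hits = list(miranda = c(150, -12), pita = c(1, -11),
                                    targetscan = c(0.5, -13)))
  expect_equal(evidence_level(pred), 3L)
  nothing <- make_evidence(hits = list(pita = c(1, -12)))
  expect_true(is.na(evidence_level(nothing)))
  # adding evidence never lowers the level
  strong_and_pred <- make_evidence(strong = TRUE, weak = TRUE,
                                   hits = list(miranda = c(150, -12),
                                               pita = c(1, -11),
                                               targetscan = c(0.5, -13)))
  expect_equal(evidence_level(strong_and_pred), 1L)
})

test_that("merging ORs flags, unions hits, and keeps the best duplicate hit", {
  experimental <- data.frame(
    mirna = c("m1", "m1"), gene = c("g1", "g1"),
    evidence_class = c("weak", "strong"), stringsAsFactors = FALSE)
  predictions <- data.frame(
    mirna = c("m1", "m1", "m2"), gene = c("g1", "g1", "g2"),
    tool = c("miranda", "miranda", "pita"),
    score = c(150, 160, 3), mfe = c(-12, -12, -15),
    stringsAsFactors = FALSE)
  merged <- merge_evidence(experimental, predictions)
  expect_equal(nrow(merged), 2L)
  r1 <- merged[merged$mirna == "m1", ]
  expect_true(r1$experimental_strong && r1$experimental_weak)
  expect_equal(r1$miranda_score, 160)   # ties on mfe keep the higher score
  expect_equal(evidence_level(r1), 1L)  # level precedence over prediction
  # lower mfe wins over higher score
  dup <- data.frame(mirna = "m3", gene = "g3",
                    tool = c("pita", "pita"), score = c(10, 1),
                    mfe = c(-8, -20), stringsAsFactors = FALSE)
  m3 <- merge_evidence(NULL, dup)
  expect_equal(m3$pita_mfe, -20)
  expect_equal(m3$pita_score, 1)
})

test_that("merging is order-independent and handles empty fragments", {
  experimental <- data.frame(mirna = "m1", gene = "g1",
                             evidence_class = "strong",
                             stringsAsFactors = FALSE)
  predictions <- data.frame(mirna = c("m2", "m1"), gene = c("g2", "g1"),
                            tool = c("pita", "miranda"),
                            score = c(1, 150), mfe = c(-12, -14),
                            stringsAsFactors = FALSE)
  a <- merge_evidence(experimental, predictions)
  b <- merge_evidence(experimental, predictions[2:1, ])
  expect_identical(a, b)
  only_exp <- merge_evidence(experimental, NULL)
  expect_equal(nrow(only_exp), 1L)
  expect_equal(evidence_level(only_exp), 1L)
  expect_equal(nrow(merge_evidence(NULL, NULL)), 0L)
})

test_that("evidence loaders parse, skip malformed rows, and respect strict", {
  tmp <- withr::local_tempdir()
  exp_path <- file.path(tmp, "exp.tsv")
  writeLines(c("mirna\tgene\tevidence_class",
               "m1\tg1\tstrong", "m2\tg2\tbogus", "m3\tg3\tweak"),
             exp_path)
  expect_warning(x <- load_experimental(exp_path), "line")
  expect_equal(nrow(x), 2L)
  expect_error(load_experimental(exp_path, strict = TRUE), "malformed")
  pred_path <- file.path(tmp, "miranda.tsv")
  writeLines(c("mirna\tgene\tscore\tmfe", "m1\tg1\t150\t-12"), pred_path)
  p <- load_predictions(list(miranda = pred_path))
  expect_equal(p$tool, "miranda")
  expect_error(load_predictions(list(bogus = pred_path)), "named by tool")
})

test_that("resolved evidence summarises levels, tool counts, and mfe", {
  merged <- merge_evidence(
    data.frame(mirna = "m1", gene = "g1", evidence_class = "weak",
               stringsAsFactors = FALSE),
    data.frame(mirna = c("m2", "m2", "m2", "m3"),
               gene = c("g2", "g2", "g2", "g3"),
               tool = c("pita", "targetscan", "rnahybrid", "pita"),
               score = c(1, 2, 3, 4), mfe = c(-12, -9, -15, -12),
               stringsAsFactors = FALSE))
  res <- resolve_evidence(merged)
  expect_equal(nrow(res), 2L)  # m3 has one tool only -> unresolved, dropped
  m2 <- res[res$mirna == "m2", ]
  expect_equal(m2$level, 3L)
  expect_equal(m2$n_tools, 3)
  expect_equal(m2$best_mfe, -15)
  all_rows <- resolve_evidence(merged, drop_unresolved = FALSE)
  expect_equal(nrow(all_rows), 3L)
})
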