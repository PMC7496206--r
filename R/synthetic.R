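#' Synthetic study generator with planted ground truth
#'
#' Emulates the inputs of a three-condition (low / moderate / high glucose)
#' miRNA + mRNA profiling study with one library per condition: abundance
#' matrices with planted glucose-response profile types, a tiered
#' miRNA-target evidence table (experimental strong / weak / consensus
#' predicted, plus decoy rows that fail the consensus rule), Ago2 IP-seq
#' abundance tables consistent with a planted IP-supported subnetwork, a
#' TF-to-miRNA regulation table, and keyword/term gene annotations. Every
#' generated object is paired with its ground truth so downstream stages can
#' be scored exactly.
#'
#' @name synthetic_data
NULL

default_profile_mix <- function() {
  c(I = 0.1, D = 0.1, M = 0.1, V = 0.1,
    LD = 0.1, LI = 0.1, HI = 0.1, HD = 0.1, FLAT = 0.2)
}

#' Simulation configuration
#'
#' Defaults describe the reference synthetic study: 200 genes, 60 miRNAs, a
#' noiseless exact 2-fold planted effect, 50 planted true MTIs with a mixed
#' evidence tier, half as many decoy prediction rows, and 40% IP support.
#'
#' @param n_genes,n_mirnas Entity counts.
#' @param profile_mix Named proportions over the nine profile classes
#'   (including FLAT); must sum to 1.
#' @param base_abundance_log_mean,base_abundance_log_sd Log2-scale location
#'   and spread of the moderate-condition abundance distribution.
#' @param min_moderate_abundance Floor applied to moderate abundances so that
#'   planted entities always survive the low-abundance filters (see the
#'   methods vignette).
#' @param effect_size_log2 Magnitude of planted log2 fold changes; must
#'   strictly exceed the log2 bounds of the downstream calling thresholds so
#'   planted types are recoverable by construction.
#' @param noise_log2_sd Standard deviation of multiplicative log2-normal
#'   noise applied per condition.
#' @param n_true_mti Number of planted true miRNA-target pairs; if `NULL`,
#'   `frac_true_mti` of all miRNA x gene pairs is used.
#' @param frac_true_mti Proportion of all pairs planted as true targets
#'   (used when `n_true_mti` is `NULL`).
#' @param evidence_tier_mix Named proportions over evidence tiers
#'   `strong`, `weak`, `predicted`; must sum to 1.
#' @param decoy_rate Decoy prediction rows emitted per true MTI (decoys
#'   always fail the consensus rule).
#' @param ip_support_prob Probability that a true MTI is Ago2-IP-detectable.
#' @param n_tfs,tf_links_per_tf,n_decoy_tfs TF layer shape: number of
#'   differentially expressed TF genes, miRNA links per TF, and flat
#'   (non-DE) decoy TFs.
#' @param annotation_prob Per-category probability that a gene carries each
#'   of the G/O/E/C keywords.
#' @param n_terms,term_prob Number of annotation term sets and per-gene
#'   membership probability.
#' @param seed Integer seed; all generator functions derive their streams
#'   from it.
#' @param calling_thresholds List of `glucomir_thresholds` the planted effect
#'   must exceed (defaults: the shipped gene and miRNA thresholds).
#'
#' @return A `glucomir_sim_config` list.
#' @export
simulation_config <- function(n_genes = 200, n_mirnas = 60,
                              profile_mix = default_profile_mix(),
                              base_abundance_log_mean = 7,
                              base_abundance_log_sd = 1,
                              min_moderate_abundance = 40,
                              effect_size_log2 = 1,
                              noise_log2_sd = 0,
                              n_true_mti = 50,
                              frac_true_mti = NULL,
                              evidence_tier_mix = c(strong = 0.2, weak = 0.2,
                                                    predicted = 0.6),
                              decoy_rate = 0.5,
                              ip_support_prob = 0.4,
                              n_tfs = 3, tf_links_per_tf = 5,
                              n_decoy_tfs = 1,
                              annotation_prob = 0.15,
                              n_terms = 20, term_prob = 0.08,
                              seed = 1,
                              calling_thresholds = list(gene_thresholds(),
                                                        mirna_thresholds())) {
  check_mix <- function(mix, levels, what) {
    if (!all(levels %in% names(mix)) || length(mix) != length(levels))
      stop(what, " must name exactly: ", paste(levels, collapse = ", "),
           call. = FALSE)
    if (any(mix < 0 | mix > 1) || abs(sum(mix) - 1) > 1e-9)
      stop(what, " proportions must lie in [0,1] and sum to 1", call. = FALSE)
    mix[levels]
  }
  profile_mix <- check_mix(profile_mix, PROFILE_TYPES, "profile_mix")
  evidence_tier_mix <- check_mix(evidence_tier_mix,
                                 c("strong", "weak", "predicted"),
                                 "evidence_tier_mix")
  needed <- max(vapply(calling_thresholds, function(th)
    max(log2(th$up_fc), -log2(th$down_fc)), 0))
  if (!(effect_size_log2 > needed))
    stop(sprintf(paste0("effect_size_log2 (%.3f) must strictly exceed the ",
                        "log2 calling bounds (%.3f): planted types would ",
                        "not be recoverable"), effect_size_log2, needed),
         call. = FALSE)
  if (noise_log2_sd < 0) stop("noise_log2_sd must be >= 0", call. = FALSE)
  if (decoy_rate < 0) stop("decoy_rate must be >= 0", call. = FALSE)
  for (p in c(ip_support_prob, annotation_prob, term_prob))
    if (p < 0 || p > 1)
      stop("probabilities must lie in [0,1]", call. = FALSE)
  structure(
    list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
         profile_mix = profile_mix,
         base_abundance_log_mean = base_abundance_log_mean,
         base_abundance_log_sd = base_abundance_log_sd,
         min_moderate_abundance = min_moderate_abundance,
         effect_size_log2 = effect_size_log2,
         noise_log2_sd = noise_log2_sd,
         n_true_mti = if (is.null(n_true_mti)) NULL else as.integer(n_true_mti),
         frac_true_mti = frac_true_mti,
         evidence_tier_mix = evidence_tier_mix,
         decoy_rate = decoy_rate,
         ip_support_prob = ip_support_prob,
         n_tfs = as.integer(n_tfs),
         tf_links_per_tf = as.integer(tf_links_per_tf),
         n_decoy_tfs = as.integer(n_decoy_tfs),
         annotation_prob = annotation_prob,
         n_terms = as.integer(n_terms), term_prob = term_prob,
         seed = as.integer(seed)),
    class = "glucomir_sim_config"
  )
}

# deterministic largest-remainder allocation of n items over proportions
allocate_counts <- function(n, mix) {
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(mix))
}

profile_signature <- function(profile) {
  sig <- list(I = c(-1, 1), D = c(1, -1), M = c(-1, -1), V = c(1, 1),
              LD = c(-1, 0), LI = c(1, 0), HI = c(0, 1), HD = c(0, -1),
              FLAT = c(0, 0))
  do.call(rbind, sig[profile])
}

#' Generate a three-condition expression matrix with planted profiles
#'
#' Moderate-condition abundances are drawn log2-normally (floored at
#' `min_moderate_abundance`); low and high abundances are the moderate value
#' shifted by the planted effect along the profile's signature, times
#' multiplicative log-normal noise.
#'
#' @param config A `glucomir_sim_config`.
#' @param kind `"gene"` or `"mirna"`.
#' @param ids Optional character ids (length `n_genes`/`n_mirnas`); defaults
#'   to synthetic ids (`g0001...`, `mir0001...`).
#'
#' @return List with `matrix` (expression data frame) and `profiles`
#'   (data frame `entity`, `profile` of the planted types).
#' @export
generate_expression <- function(config, kind = c("gene", "mirna"),
                                ids = NULL) {
  kind <- match.arg(kind)
  n <- if (kind == "gene") config$n_genes else config$n_mirnas
  set.seed(config$seed + if (kind == "gene") 0L else 1L)
  if (is.null(ids)) {
    ids <- if (kind == "gene")
      sprintf("g%04d", seq_len(n)) else sprintf("mir%04d", seq_len(n))
  }
  if (length(ids) != n) stop("ids length must equal entity count",
                             call. = FALSE)
  counts <- allocate_counts(n, config$profile_mix)
  profile <- sample(rep(names(counts), counts))
  sig <- profile_signature(profile)
  moderate <- pmax(2^stats::rnorm(n, config$base_abundance_log_mean,
                                  config$base_abundance_log_sd),
                   config$min_moderate_abundance)
  noise <- function() {
    if (config$noise_log2_sd == 0) rep(0, n)
    else stats::rnorm(n, 0, config$noise_log2_sd)
  }
  low <- moderate * 2^(sig[, 1L] * config$effect_size_log2 + noise())
  high <- moderate * 2^(sig[, 2L] * config$effect_size_log2 + noise())
  list(
    matrix = expression_matrix(ids, low, moderate, high),
    profiles = data.frame(entity = ids, profile = profile,
                          stringsAsFactors = FALSE)
  )
}

#' Plant the true regulatory network
#'
#' True MTIs are sampled among non-FLAT inverse-profile pairs only: a planted
#' pair is then recoverable by the inverse-expression rule by construction,
#' which is what makes exact precision/recall scoring against truth
#' meaningful. Tiers are allocated deterministically by the tier mix; IP
#' support is an independent coin per true pair.
#'
#' @param config A `glucomir_sim_config`.
#' @param gene_profiles,mirna_profiles Planted profile tables from
#'   [generate_expression()].
#'
#' @return A `glucomir_truth` list: `true_mtis` (data frame `mirna`, `gene`,
#'   `tier`), `ip_supported` (data frame `mirna`, `gene`), `gene_profiles`,
#'   `mirna_profiles`.
#' @export
generate_truth <- function(config, gene_profiles, mirna_profiles) {
  set.seed(config$seed + 2L)
  n_true <- if (!is.null(config$n_true_mti)) config$n_true_mti
            else round(config$frac_true_mti * config$n_genes * config$n_mirnas)
  m_ok <- mirna_profiles[mirna_profiles$profile != "FLAT", ]
  g_ok <- gene_profiles[gene_profiles$profile != "FLAT", ]
  # all candidate inverse pairs
  cand <- do.call(rbind, lapply(seq_len(nrow(m_ok)), function(i) {
    want <- inverse_type(m_ok$profile[i])
    g <- g_ok$entity[g_ok$profile == want]
    if (!length(g)) return(NULL)
    data.frame(mirna = m_ok$entity[i], gene = g, stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) < n_true)
    stop("not enough inverse-profile pairs to plant ", n_true, " true MTIs",
         call. = FALSE)
  pick <- cand[sample(nrow(cand), n_true), , drop = FALSE]
  tier_counts <- allocate_counts(n_true, config$evidence_tier_mix)
  pick$tier <- sample(rep(names(tier_counts), tier_counts))
  ip <- pick[stats::runif(n_true) < config$ip_support_prob,
             c("mirna", "gene"), drop = FALSE]
  rownames(pick) <- rownames(ip) <- NULL
  structure(
    list(true_mtis = pick, ip_supported = ip,
         gene_profiles = gene_profiles, mirna_profiles = mirna_profiles),
    class = "glucomir_truth"
  )
}

#' Generate experimental and prediction evidence tables from planted truth
#'
#' Every true MTI is emitted with evidence matching its tier: strong/weak
#' tiers as experimental rows, predicted tiers as hits from at least three
#' tools with passing miRanda scores and free energies. Decoy rows
#' (`decoy_rate` per true MTI, sampled uniformly from non-true pairs) always
#' violate the consensus rule, by one of three constructions: only two
#' supporting tools, a sub-threshold miRanda score, or all free energies
#' above the cutoff.
#'
#' @param truth A `glucomir_truth`.
#' @param config A `glucomir_sim_config`.
#' @return List `experimental` (`mirna`, `gene`, `evidence_class`) and
#'   `predictions` (`mirna`, `gene`, `tool`, `score`, `mfe`), both in the
#'   loader formats of [load_experimental()] / [load_predictions()].
#' @export
generate_mti_evidence <- function(truth, config) {
  set.seed(config$seed + 3L)
  tm <- truth$true_mtis
  exper <- tm[tm$tier %in% c("strong", "weak"), , drop = FALSE]
  experimental <- data.frame(mirna = exper$mirna, gene = exper$gene,
                             evidence_class = exper$tier,
                             stringsAsFactors = FALSE)
  hit_rows <- function(mirna, gene, tools, score_rng, mfe_rng) {
    data.frame(
      mirna = mirna, gene = gene, tool = tools,
      score = round(stats::runif(length(tools), score_rng[1], score_rng[2]), 1),
      mfe = round(stats::runif(length(tools), mfe_rng[1], mfe_rng[2]), 2),
      stringsAsFactors = FALSE
    )
  }
  pred <- tm[tm$tier == "predicted", , drop = FALSE]
  pred_rows <- lapply(seq_len(nrow(pred)), function(i) {
    k <- sample(3:4, 1L)
    tools <- sample(MTI_TOOLS, k)
    rows <- hit_rows(pred$mirna[i], pred$gene[i], tools,
                     score_rng = c(150, 200), mfe_rng = c(-25, -10.5))
    rows
  })
  n_decoys <- round(config$decoy_rate * nrow(tm))
  decoy_rows <- list()
  if (n_decoys > 0) {
    all_m <- truth$mirna_profiles$entity
    all_g <- truth$gene_profiles$entity
    true_key <- paste(tm$mirna, tm$gene)
    pairs <- character(0)
    guard <- 0L
    while (length(pairs) < n_decoys && guard < 100L) {
      m <- sample(all_m, n_decoys, replace = TRUE)
      g <- sample(all_g, n_decoys, replace = TRUE)
      key <- paste(m, g)
      keep <- !(key %in% true_key) & !(key %in% pairs)
      pairs <- c(pairs, unique(key[keep]))
      guard <- guard + 1L
    }
    pairs <- pairs[seq_len(min(n_decoys, length(pairs)))]
    parts <- strsplit(pairs, " ", fixed = TRUE)
    decoy_rows <- lapply(parts, function(p) {
      mode <- sample(c("two_tools", "low_miranda", "weak_mfe"), 1L)
      if (mode == "two_tools") {
        tools <- sample(MTI_TOOLS, 2L)
        hit_rows(p[1], p[2], tools, c(150, 200), c(-25, -10.5))
      } else if (mode == "low_miranda") {
        tools <- c("miranda", sample(setdiff(MTI_TOOLS, "miranda"), 2L))
        rows <- hit_rows(p[1], p[2], tools, c(150, 200), c(-25, -10.5))
        rows$score[rows$tool == "miranda"] <-
          round(stats::runif(1, 50, 139), 1)
        rows
      } else {
        tools <- sample(MTI_TOOLS, 3L)
        hit_rows(p[1], p[2], tools, c(150, 200), c(-9.5, -2))
      }
    })
  }
  predictions <- do.call(rbind, c(pred_rows, decoy_rows))
  if (is.null(predictions))
    predictions <- data.frame(mirna = character(), gene = character(),
                              tool = character(), score = numeric(),
                              mfe = numeric(), stringsAsFactors = FALSE)
  rownames(predictions) <- NULL
  list(experimental = experimental, predictions = predictions)
}

#' Generate Ago2 IP-seq abundance tables consistent with planted IP support
#'
#' Entities participating in an IP-supported pair receive IP abundances
#' above the Ago2 filter floors (gene FPKM >= 8, miRNA RPM >= 100); all
#' other entities fall strictly below them.
#'
#' @param truth A `glucomir_truth`.
#' @param config A `glucomir_sim_config`.
#' @return List `gene_ip` and `mirna_ip`: data frames `id`, `ip` (single
#'   IP-library abundance column).
#' @export
generate_ago2_tables <- function(truth, config) {
  set.seed(config$seed + 4L)
  one <- function(ids, supported, floor_val, high_rng) {
    inside <- ids %in% supported
    val <- numeric(length(ids))
    val[inside] <- round(stats::runif(sum(inside), high_rng[1], high_rng[2]), 2)
    val[!inside] <- round(stats::runif(sum(!inside), 0, floor_val * 0.98), 2)
    data.frame(id = ids, ip = val, stringsAsFactors = FALSE)
  }
  list(
    gene_ip = one(truth$gene_profiles$entity,
                  unique(truth$ip_supported$gene), 8, c(8, 200)),
    mirna_ip = one(truth$mirna_profiles$entity,
                   unique(truth$ip_supported$mirna), 100, c(100, 5000))
  )
}

#' Generate a TF-to-miRNA regulation table with planted links
#'
#' Plants `n_tfs` hub TFs among non-FLAT genes, each linked to
#' `tf_links_per_tf` non-FLAT miRNAs, plus `n_decoy_tfs` FLAT (non-DE) decoy
#' TFs whose rows downstream filtering must drop.
#'
#' @param truth A `glucomir_truth`.
#' @param config A `glucomir_sim_config`.
#' @return List `tf_table` (data frame `tf_gene`, `mirna`, `sign`) and
#'   `tf_links` (the planted true subset).
#' @export
generate_tf_table <- function(truth, config) {
  set.seed(config$seed + 5L)
  de_genes <- truth$gene_profiles$entity[truth$gene_profiles$profile != "FLAT"]
  flat_genes <-
    truth$gene_profiles$entity[truth$gene_profiles$profile == "FLAT"]
  de_mirnas <-
    truth$mirna_profiles$entity[truth$mirna_profiles$profile != "FLAT"]
  n_tfs <- min(config$n_tfs, length(de_genes))
  tfs <- sample(de_genes, n_tfs)
  links <- do.call(rbind, lapply(tfs, function(tf) {
    m <- sample(de_mirnas, min(config$tf_links_per_tf, length(de_mirnas)))
    data.frame(tf_gene = tf, mirna = m,
               sign = sample(c("activate", "repress"), length(m),
                             replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  decoys <- NULL
  n_dec <- min(config$n_decoy_tfs, length(flat_genes))
  if (n_dec > 0) {
    dec_tfs <- sample(flat_genes, n_dec)
    decoys <- do.call(rbind, lapply(dec_tfs, function(tf) {
      m <- sample(de_mirnas, min(2L, length(de_mirnas)))
      data.frame(tf_gene = tf, mirna = m,
                 sign = sample(c("activate", "repress"), length(m),
                               replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  tf_table <- rbind(links, decoys)
  rownames(tf_table) <- rownames(links) <- NULL
  list(tf_table = tf_table, tf_links = links)
}

#' Generate keyword and term annotations for genes
#'
#' Each gene independently carries each of the G/O/E/C functional keywords
#' (glucose/carbon/insulin; ion/calcium; exocytosis/homeostasis;
#' CREB/cAMP/transcription factor) and joins each of `n_terms` term sets.
#'
#' @param gene_ids Character gene ids.
#' @param config A `glucomir_sim_config`.
#' @return Annotation data frame `gene`, `categories`, `terms`
#'   (comma-separated fields, possibly empty).
#' @export
generate_annotations <- function(gene_ids, config) {
  set.seed(config$seed + 6L)
  cats <- c("G", "O", "E", "C")
  categories <- vapply(gene_ids, function(g) {
    has <- cats[stats::runif(4) < config$annotation_prob]
    paste(has, collapse = ",")
  }, "", USE.NAMES = FALSE)
  term_ids <- sprintf("term%02d", seq_len(config$n_terms))
  member <- matrix(stats::runif(length(gene_ids) * config$n_terms) <
                     config$term_prob,
                   nrow = length(gene_ids))
  terms <- apply(member, 1L, function(row)
    paste(term_ids[row], collapse = ","))
  data.frame(gene = gene_ids, categories = categories, terms = terms,
             stringsAsFactors = FALSE)
}

#' Plant a term set enriched in a query gene set
#'
#' Builds random background term sets plus one term whose membership
#' probability is `fold` times higher inside `query` than outside - the
#' positive control for over-representation testing.
#'
#' @param background,query Character gene id vectors (`query` inside
#'   `background`).
#' @param fold Enrichment factor of the planted term (default 5).
#' @param base_prob Membership probability outside the query (default 0.1).
#' @param n_null_terms Number of unenriched terms drawn at `base_prob`
#'   everywhere.
#' @return Named list of term sets; the planted one is `"planted_term"`.
#' @export
plant_enriched_term <- function(background, query, fold = 5,
                                base_prob = 0.1, n_null_terms = 10) {
  stopifnot(all(query %in% background))
  p <- stats::setNames(rep(base_prob, length(background)), background)
  p[query] <- min(1, fold * base_prob)
  planted <- background[stats::runif(length(background)) < p]
  nulls <- lapply(seq_len(n_null_terms), function(i)
    background[stats::runif(length(background)) < base_prob])
  names(nulls) <- sprintf("null_term%02d", seq_len(n_null_terms))
  c(list(planted_term = planted), nulls)
}

#' Simulate a complete study
#'
#' Runs every generator in a fixed order with seeds derived from
#' `config$seed`, so the whole bundle is bit-reproducible.
#'
#' @param config A `glucomir_sim_config`.
#' @param gene_ids,mirna_ids Optional real id lists.
#' @return A `glucomir_simulation` list: `gene_expr`, `mirna_expr`, `truth`,
#'   `experimental`, `predictions`, `gene_ip`, `mirna_ip`, `tf_table`,
#'   `annotations`, `config`.
#' @export
simulate_study <- function(config = simulation_config(), gene_ids = NULL,
                           mirna_ids = NULL) {
  genes <- generate_expression(config, "gene", ids = gene_ids)
  mirnas <- generate_expression(config, "mirna", ids = mirna_ids)
  truth <- generate_truth(config, genes$profiles, mirnas$profiles)
  evidence <- generate_mti_evidence(truth, config)
  ago2 <- generate_ago2_tables(truth, config)
  tf <- generate_tf_table(truth, config)
  annotations <- generate_annotations(genes$profiles$entity, config)
  truth$tf_links <- tf$tf_links
  structure(
    list(gene_expr = genes$matrix, mirna_expr = mirnas$matrix,
         truth = truth,
         experimental = evidence$experimental,
         predictions = evidence$predictions,
         gene_ip = ago2$gene_ip, mirna_ip = ago2$mirna_ip,
         tf_table = tf$tf_table, annotations = annotations,
         config = config),
    class = "glucomir_simulation"
  )
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Expression, evidence, IP, TF and annotation tables are written as TSV;
#' ground truth as a pair-list TSV plus a JSON sidecar of per-entity profile
#' types.
#'
#' @param sim A `glucomir_simulation`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gene_expr = file.path(dir, "gene_expression.tsv"),
    mirna_expr = file.path(dir, "mirna_expression.tsv"),
    experimental = file.path(dir, "mti_experimental.tsv"),
    gene_ip = file.path(dir, "ago2_gene_ip.tsv"),
    mirna_ip = file.path(dir, "ago2_mirna_ip.tsv"),
    tf_table = file.path(dir, "tf_mirna.tsv"),
    annotations = file.path(dir, "gene_annotations.tsv"),
    truth_mtis = file.path(dir, "truth_mtis.tsv"),
    truth_profiles = file.path(dir, "truth_profiles.json")
  )
  write_expression(sim$gene_expr, paths[["gene_expr"]])
  write_expression(sim$mirna_expr, paths[["mirna_expr"]])
  write_tsv(sim$experimental, paths[["experimental"]])
  write_tsv(sim$gene_ip, paths[["gene_ip"]])
  write_tsv(sim$mirna_ip, paths[["mirna_ip"]])
  write_tsv(sim$tf_table, paths[["tf_table"]])
  write_tsv(sim$annotations, paths[["annotations"]])
  write_tsv(sim$truth$true_mtis, paths[["truth_mtis"]])
  for (tool in MTI_TOOLS) {
    p <- file.path(dir, paste0("predictions_", tool, ".tsv"))
    paths[[paste0("predictions_", tool)]] <- p
    rows <- sim$predictions[sim$predictions$tool == tool,
                            c("mirna", "gene", "score", "mfe")]
    write_tsv(rows, p)
  }
  jsonlite::write_json(
    list(
      gene_profiles = stats::setNames(
        as.list(sim$truth$gene_profiles$profile),
        sim$truth$gene_profiles$entity),
      mirna_profiles = stats::setNames(
        as.list(sim$truth$mirna_profiles$profile),
        sim$truth$mirna_profiles$entity)
    ),
    paths[["truth_profiles"]], auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
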