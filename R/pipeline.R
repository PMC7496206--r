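#' Pipeline orchestration
#'
#' A single configuration object names every input table and holds every
#' tunable constant; [run_pipeline()] executes the stages in order -
#' differential calling, profile classification, evidence resolution,
#' inverse-expression pairing, the TF layer, Ago2 promotion, enrichment -
#' writing each stage's tables plus a provenance manifest under one output
#' directory. A rerun with the same configuration and seed is byte-identical.
#'
#' @name pipeline
NULL

#' Assemble and validate a pipeline configuration
#'
#' @param paths Named list of input paths: required `gene_expr`,
#'   `mirna_expr`; optional `experimental`, `predictions` (named list per
#'   tool), `gene_ip`, `mirna_ip`, `tf_table`, `annotations`, `gmt`.
#' @param out_dir Output directory.
#' @param gene_thresholds,mirna_thresholds `glucomir_thresholds` objects.
#' @param consensus List of consensus settings passed to
#'   [consensus_accept()] (`min_tools`, `min_miranda_score`, `mfe_cutoff`,
#'   `require_miranda`, `mfe_all_hits`).
#' @param ip An [ip_filter()].
#' @param hub_min_targets Hub degree threshold (strict `>`).
#' @param top_terms Enrichment truncation.
#' @param correction Multiple-testing correction for enrichment.
#' @param seed Integer seed recorded in the manifest.
#' @param strict Abort on malformed input rows instead of skipping.
#' @return A `glucomir_pipeline_config` list.
#' @export
pipeline_config <- function(paths, out_dir,
                            gene_thresholds = glucomir::gene_thresholds(),
                            mirna_thresholds = glucomir::mirna_thresholds(),
                            consensus = list(min_tools = 3,
                                             min_miranda_score = 140,
                                             mfe_cutoff = -10),
                            ip = ip_filter(),
                            hub_min_targets = 10,
                            top_terms = 20,
                            correction = "bh",
                            seed = 1,
                            strict = FALSE) {
  need <- c("gene_expr", "mirna_expr")
  if (!all(need %in% names(paths)))
    stop("paths must name at least: ", paste(need, collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(gene_thresholds, "glucomir_thresholds"),
            inherits(mirna_thresholds, "glucomir_thresholds"),
            inherits(ip, "glucomir_ip_filter"))
  structure(
    list(paths = paths, out_dir = out_dir,
         gene_thresholds = gene_thresholds,
         mirna_thresholds = mirna_thresholds,
         consensus = consensus, ip = ip,
         hub_min_targets = hub_min_targets, top_terms = top_terms,
         correction = correction, seed = as.integer(seed),
         strict = isTRUE(strict)),
    class = "glucomir_pipeline_config"
  )
}

flat_paths <- function(paths) {
  unlist(paths, use.names = TRUE)
}

# fingerprint of the analysis parameters (not the file locations, so the
# same analysis run from a different directory yields the same manifest)
config_fingerprint <- function(config) {
  clean <- config
  clean$out_dir <- NULL
  clean$paths <- NULL
  json <- jsonlite::toJSON(unclass(clean), auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full reconstruction pipeline
#'
#' Fails before any stage runs if a referenced input file is missing. Stage
#' outputs are written as TSV under `config$out_dir`; the manifest JSON
#' records the configuration fingerprint, seed, and row counts in/out per
#' stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results (`gene_calls`,
#'   `mirna_calls`, `gene_profiles`, `mirna_profiles`, `evidence`, `edges`,
#'   `networks`, `hubs`, `tf_edges`, `level4`, `enrichment`,
#'   `keyword_nets`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "glucomir_pipeline_config"))
  files <- flat_paths(config$paths)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing input files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  counts <- list()

  # --- differential expression ---------------------------------------
  gene_expr <- read_expression(config$paths$gene_expr)
  mirna_expr <- read_expression(config$paths$mirna_expr)
  counts$genes_in <- nrow(gene_expr)
  counts$mirnas_in <- nrow(mirna_expr)
  gene_calls <- list(
    low = call_differential(gene_expr, config$gene_thresholds, "low_vs_mod"),
    high = call_differential(gene_expr, config$gene_thresholds, "high_vs_mod")
  )
  mirna_calls <- list(
    low = call_differential(mirna_expr, config$mirna_thresholds,
                            "low_vs_mod"),
    high = call_differential(mirna_expr, config$mirna_thresholds,
                             "high_vs_mod")
  )
  write_tsv(rbind(gene_calls$low, gene_calls$high), out("gene_calls.tsv"))
  write_tsv(rbind(mirna_calls$low, mirna_calls$high), out("mirna_calls.tsv"))

  # --- profiles -------------------------------------------------------
  gene_profiles <- suppressWarnings(
    classify_entities(gene_calls$low, gene_calls$high))
  mirna_profiles <- suppressWarnings(
    classify_entities(mirna_calls$low, mirna_calls$high))
  write_tsv(gene_profiles, out("gene_profiles.tsv"))
  write_tsv(mirna_profiles, out("mirna_profiles.tsv"))
  tc <- data.frame(profile = PROFILE_TYPES,
                   genes = type_counts(gene_profiles),
                   mirnas = type_counts(mirna_profiles),
                   row.names = NULL, stringsAsFactors = FALSE)
  write_tsv(tc, out("type_counts.tsv"))
  counts$de_genes <- sum(gene_profiles$profile != "FLAT")
  counts$de_mirnas <- sum(mirna_profiles$profile != "FLAT")

  # --- evidence -------------------------------------------------------
  experimental <- NULL
  predictions <- NULL
  if (!is.null(config$paths$experimental))
    experimental <- load_experimental(config$paths$experimental,
                                      strict = config$strict)
  if (!is.null(config$paths$predictions))
    predictions <- load_predictions(config$paths$predictions,
                                    strict = config$strict)
  evidence_wide <- merge_evidence(experimental, predictions)
  evidence <- do.call(resolve_evidence,
                      c(list(evidence_wide), config$consensus))
  write_tsv(evidence, out("evidence.tsv"))
  counts$evidence_candidates <- nrow(evidence_wide)
  counts$evidence_resolved <- nrow(evidence)

  # --- network --------------------------------------------------------
  edges <- build_mti_edges(mirna_profiles, gene_profiles, evidence)
  nets <- split_networks(edges)
  export_network(edges, out("network_edges.tsv"), "edge-tsv")
  export_network(edges, out("network.sif"), "sif")
  write_tsv(nets$summary, out("network_summary.tsv"))
  counts$mti_edges <- nrow(edges)
  hubs <- lapply(nets[c("high_dn", "high_up", "low_dn", "low_up")],
                 hub_mirnas, min_targets = config$hub_min_targets)

  # --- TF layer -------------------------------------------------------
  tf_edges <- NULL
  if (!is.null(config$paths$tf_table)) {
    tf_table <- read_tf_table(config$paths$tf_table)
    tf_edges <- suppressWarnings(
      build_tf_layer(tf_table, gene_profiles, mirna_profiles))
    write_tsv(tf_edges, out("tf_edges.tsv"))
    counts$tf_edges <- nrow(tf_edges)
  }
  export_network(edges, out("network.graphml"), "graphml",
                 tf_edges = tf_edges)

  # --- Ago2 -----------------------------------------------------------
  level4 <- NULL
  if (!is.null(config$paths$gene_ip) && !is.null(config$paths$mirna_ip)) {
    gene_ip <- read_tsv(config$paths$gene_ip, "id")
    mirna_ip <- read_tsv(config$paths$mirna_ip, "id")
    supported <- ip_supported_entities(gene_ip, mirna_ip, config$ip)
    level4 <- promote_level4(edges, supported)
    export_network(level4, out("level4_edges.tsv"), "edge-tsv")
    write_tsv(attr(level4, "reduction"), out("ago2_reduction.tsv"))
    counts$level4_edges <- nrow(level4)
  }

  # --- enrichment + keywords -----------------------------------------
  enrichment <- NULL
  keyword_nets <- NULL
  if (!is.null(config$paths$annotations)) {
    annotations <- read_annotations(config$paths$annotations)
    keyword_nets <- keyword_networks(edges, annotations)
    for (cat in names(keyword_nets))
      export_network(keyword_nets[[cat]],
                     out(sprintf("network_%s_edges.tsv", cat)), "edge-tsv")
    term_sets <- if (!is.null(config$paths$gmt)) {
      read_gmt(config$paths$gmt)
    } else {
      terms <- annotation_terms(annotations)
      all_terms <- sort(unique(unlist(terms)))
      stats::setNames(lapply(all_terms, function(t)
        names(terms)[vapply(terms, function(v) t %in% v, TRUE)]), all_terms)
    }
    # background: filter-passing expressed genes; query: network genes
    expressed <- gene_profiles$entity[gene_profiles$note != "filtered_both"]
    query <- intersect(unique(edges$gene), expressed)
    if (length(query) && length(term_sets)) {
      enrichment <- enrich(query, term_sets, expressed,
                           correction = config$correction,
                           top = config$top_terms)
      write_tsv(enrichment, out("enrichment.tsv"))
      counts$enriched_terms <- nrow(enrichment)
    }
  }

  # --- manifest -------------------------------------------------------
  manifest <- list(
    config_md5 = config_fingerprint(config),
    seed = config$seed,
    stage_counts = counts,
    condition_semantics = paste(
      "types changed in both comparisons contribute to both conditions'",
      "networks")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(
    gene_calls = gene_calls, mirna_calls = mirna_calls,
    gene_profiles = gene_profiles, mirna_profiles = mirna_profiles,
    evidence = evidence, edges = edges, networks = nets, hubs = hubs,
    tf_edges = tf_edges, level4 = level4, enrichment = enrichment,
    keyword_nets = keyword_nets, manifest = manifest
  ))
}

#' Simulate a study to disk and run the pipeline on it
#'
#' Convenience wrapper used by the analysis drivers: writes a simulated
#' study under `input_dir`, assembles a matching configuration, and runs the
#' pipeline into `out_dir`.
#'
#' @param sim_config A [simulation_config()].
#' @param input_dir,out_dir Directories for simulated inputs and pipeline
#'   outputs.
#' @param ... Further arguments to [pipeline_config()].
#' @return List with `sim` (the simulation), `config`, and `result` (the
#'   [run_pipeline()] output).
#' @export
run_simulated_pipeline <- function(sim_config = simulation_config(),
                                   input_dir = tempfile("glucomir_in_"),
                                   out_dir = tempfile("glucomir_out_"),
                                   ...) {
  sim <- simulate_study(sim_config)
  paths <- write_simulation(sim, input_dir)
  config <- pipeline_config(
    paths = list(
      gene_expr = paths[["gene_expr"]],
      mirna_expr = paths[["mirna_expr"]],
      experimental = paths[["experimental"]],
      predictions = as.list(stats::setNames(
        paths[paste0("predictions_", MTI_TOOLS)], MTI_TOOLS)),
      gene_ip = paths[["gene_ip"]],
      mirna_ip = paths[["mirna_ip"]],
      tf_table = paths[["tf_table"]],
      annotations = paths[["annotations"]]
    ),
    out_dir = out_dir, seed = sim_config$seed, ...
  )
  result <- run_pipeline(config)
  list(sim = sim, config = config, result = result)
}
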