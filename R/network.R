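#' Inverse-expression network reconstruction
#'
#' High-confidence regulatory edges join a differentially expressed miRNA to
#' a differentially expressed gene when (a) the pair carries resolved MTI
#' evidence (level 1-3) and (b) the gene's glucose-response profile is the
#' inverse of the miRNA's - the miRNA acting as a negative regulator. Edges
#' are built per condition (low / high glucose); a miRNA whose profile does
#' not change under a condition (e.g. an LD type at high glucose)
#' contributes no edge to that condition's network. Edges split into four
#' sub-networks by condition and miRNA direction (high-DN, high-UP, low-DN,
#' low-UP), mirroring how condition-specific down-/up-regulated miRNA
#' networks are reported.
#'
#' @name network
NULL

#' Direction of a profile under one condition
#'
#' @param profile Character profile types.
#' @param condition `"low"` or `"high"`.
#' @return `"up"`, `"down"`, or `"nc"` per entity.
#' @export
profile_direction <- function(profile, condition = c("low", "high")) {
  condition <- match.arg(condition)
  sig <- profile_signature(profile)
  s <- sig[, if (condition == "low") 1L else 2L]
  c("down", "nc", "up")[s + 2L]
}

empty_edges <- function() {
  data.frame(mirna = character(), gene = character(),
             condition = character(), mirna_direction = character(),
             level = integer(), mirna_profile = character(),
             gene_profile = character(), stringsAsFactors = FALSE)
}

#' Pair DE miRNAs with DE genes under the inverse-expression rule
#'
#' An edge (m, g) is created for the requested condition iff the pair has a
#' resolved evidence level in 1-3, both entities are non-FLAT, the gene's
#' profile is the inverse type of the miRNA's, and the miRNA is actually
#' changed (up or down) under that condition. Evidence rows naming ids
#' absent from the profile tables are skipped with a counting warning.
#'
#' @param mirna_profiles,gene_profiles Data frames `entity`, `profile`
#'   (e.g. from [classify_entities()]).
#' @param evidence Resolved evidence (`mirna`, `gene`, `level`) from
#'   [resolve_evidence()].
#' @param condition `"low"` or `"high"`.
#' @return Edge data frame `mirna`, `gene`, `condition`, `mirna_direction`,
#'   `level`, `mirna_profile`, `gene_profile`, deduplicated and sorted by
#'   (mirna, gene).
#' @export
pair_inverse <- function(mirna_profiles, gene_profiles, evidence,
                         condition = c("low", "high")) {
  condition <- match.arg(condition)
  if (nrow(evidence) == 0L) return(empty_edges())
  evidence <- evidence[!is.na(evidence$level) & evidence$level %in% 1:3, ,
                       drop = FALSE]
  mp <- stats::setNames(mirna_profiles$profile, mirna_profiles$entity)
  gp <- stats::setNames(gene_profiles$profile, gene_profiles$entity)
  known <- evidence$mirna %in% names(mp) & evidence$gene %in% names(gp)
  if (any(!known))
    warning(sum(!known), " evidence rows reference unknown ids (skipped)",
            call. = FALSE)
  evidence <- evidence[known, , drop = FALSE]
  if (nrow(evidence) == 0L) return(empty_edges())
  m_prof <- unname(mp[evidence$mirna])
  g_prof <- unname(gp[evidence$gene])
  ok <- m_prof != "FLAT" & g_prof != "FLAT"
  ok[ok] <- g_prof[ok] == inverse_type(m_prof[ok])
  direction <- rep("nc", nrow(evidence))
  direction[ok] <- profile_direction(m_prof[ok], condition)
  keep <- ok & direction != "nc"
  out <- data.frame(
    mirna = evidence$mirna[keep], gene = evidence$gene[keep],
    condition = condition, mirna_direction = direction[keep],
    level = as.integer(evidence$level[keep]),
    mirna_profile = m_prof[keep], gene_profile = g_prof[keep],
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(out[, c("mirna", "gene")]), , drop = FALSE]
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the full MTI edge set over both conditions
#'
#' @inheritParams pair_inverse
#' @param conditions Conditions to build (default both).
#' @return Combined edge data frame.
#' @export
build_mti_edges <- function(mirna_profiles, gene_profiles, evidence,
                            conditions = c("low", "high")) {
  out <- do.call(rbind, lapply(conditions, function(cond)
    pair_inverse(mirna_profiles, gene_profiles, evidence, cond)))
  if (is.null(out)) out <- empty_edges()
  rownames(out) <- NULL
  out
}

#' Split edges into the four condition x direction sub-networks
#'
#' @param edges Edge data frame from [build_mti_edges()].
#' @return List with elements `high_dn`, `high_up`, `low_dn`, `low_up`
#'   (edge frames) and `summary` (data frame `network`, `n_mirnas`,
#'   `n_genes`, `n_edges`).
#' @export
split_networks <- function(edges) {
  pick <- function(cond, dir) {
    out <- edges[edges$condition == cond & edges$mirna_direction == dir, ,
                 drop = FALSE]
    rownames(out) <- NULL
    out
  }
  nets <- list(high_dn = pick("high", "down"), high_up = pick("high", "up"),
               low_dn = pick("low", "down"), low_up = pick("low", "up"))
  summary <- data.frame(
    network = names(nets),
    n_mirnas = vapply(nets, function(e) length(unique(e$mirna)), 0L),
    n_genes = vapply(nets, function(e) length(unique(e$gene)), 0L),
    n_edges = vapply(nets, nrow, 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  c(nets, list(summary = summary))
}

#' Hub miRNAs of a sub-network
#'
#' miRNAs regulating strictly more than `min_targets` genes, ranked by
#' out-degree (ties broken by id) - e.g. with the default of 10, the "key
#' miRNA" notion of regulating more than 10 genes under one condition.
#'
#' @param edges Edge data frame.
#' @param min_targets Degree threshold (strict `>`, default 10).
#' @return Data frame `mirna`, `n_targets`, ranked.
#' @export
hub_mirnas <- function(edges, min_targets = 10) {
  if (nrow(edges) == 0L)
    return(data.frame(mirna = character(), n_targets = integer(),
                      stringsAsFactors = FALSE))
  deg <- table(edges$mirna)
  deg <- deg[deg > min_targets]
  out <- data.frame(mirna = names(deg), n_targets = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TF-to-miRNA regulatory layer
#'
#' Keeps a TF table row as an edge iff the TF gene is differentially
#' expressed (non-FLAT profile) and the miRNA is a DE miRNA (non-FLAT). The
#' edge carries the table's regulation sign and both profiles. TFs absent
#' from the gene expression matrix are skipped with a warning.
#'
#' @param tf_table Data frame `tf_gene`, `mirna`, `sign` (see
#'   [read_tf_table()]).
#' @param gene_profiles,mirna_profiles Profile tables.
#' @return Edge data frame `tf_gene`, `mirna`, `sign`, `tf_profile`,
#'   `mirna_profile`, sorted by (tf_gene, mirna).
#' @export
build_tf_layer <- function(tf_table, gene_profiles, mirna_profiles) {
  gp <- stats::setNames(gene_profiles$profile, gene_profiles$entity)
  mp <- stats::setNames(mirna_profiles$profile, mirna_profiles$entity)
  known <- tf_table$tf_gene %in% names(gp) & tf_table$mirna %in% names(mp)
  if (any(!known))
    warning(sum(!known), " TF rows reference ids absent from the ",
            "expression matrices (skipped)", call. = FALSE)
  tf_table <- tf_table[known, , drop = FALSE]
  tfp <- unname(gp[tf_table$tf_gene])
  mip <- unname(mp[tf_table$mirna])
  keep <- tfp != "FLAT" & mip != "FLAT"
  out <- data.frame(
    tf_gene = tf_table$tf_gene[keep], mirna = tf_table$mirna[keep],
    sign = tf_table$sign[keep], tf_profile = tfp[keep],
    mirna_profile = mip[keep], stringsAsFactors = FALSE
  )
  out <- out[!duplicated(out[, c("tf_gene", "mirna")]), , drop = FALSE]
  out <- out[order(out$tf_gene, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

edges_to_igraph <- function(edges, tf_edges = NULL) {
  mti <- data.frame(from = edges$mirna, to = edges$gene,
                    edge_kind = "mti",
                    interaction = paste0("mti_L", edges$level),
                    condition = edges$condition,
                    mirna_direction = edges$mirna_direction,
                    level = edges$level, stringsAsFactors = FALSE)
  all_edges <- mti
  if (!is.null(tf_edges) && nrow(tf_edges)) {
    tfe <- data.frame(from = tf_edges$tf_gene, to = tf_edges$mirna,
                      edge_kind = "tf_mirna", interaction = "tf_mirna",
                      condition = NA_character_,
                      mirna_direction = NA_character_,
                      level = NA_integer_, stringsAsFactors = FALSE)
    all_edges <- rbind(all_edges, tfe)
  }
  nodes <- data.frame(name = unique(c(all_edges$from, all_edges$to)),
                      stringsAsFactors = FALSE)
  node_type <- rep("gene", nrow(nodes))
  node_type[nodes$name %in% edges$mirna] <- "mirna"
  if (!is.null(tf_edges)) {
    node_type[nodes$name %in% tf_edges$mirna] <- "mirna"
    node_type[nodes$name %in% tf_edges$tf_gene] <- "tf_gene"
  }
  nodes$node_type <- node_type
  igraph::graph_from_data_frame(all_edges, directed = TRUE,
                                vertices = nodes)
}

#' Export a network to standard graph formats
#'
#' * `sif` - Cytoscape simple interaction format; interaction labels are
#'   `mti_L1`..`mti_L4` and `tf_mirna`.
#' * `graphml` - full node/edge attributes, written via igraph.
#' * `edge-tsv` - a plain TSV whose write-then-read round trip reproduces
#'   the edge set exactly (see [read_edge_tsv()]).
#'
#' @param edges MTI edge data frame.
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"`, or `"edge-tsv"`.
#' @param tf_edges Optional TF layer from [build_tf_layer()] (included in
#'   `sif`/`graphml`).
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("sif", "graphml",
                                                   "edge-tsv"),
                           tf_edges = NULL) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    write_tsv(edges, path)
  } else if (format == "sif") {
    lines <- character()
    if (nrow(edges))
      lines <- paste(edges$mirna, paste0("mti_L", edges$level), edges$gene)
    if (!is.null(tf_edges) && nrow(tf_edges))
      lines <- c(lines, paste(tf_edges$tf_gene, "tf_mirna", tf_edges$mirna))
    writeLines(lines, path)
  } else {
    if (nrow(edges) == 0L && (is.null(tf_edges) || nrow(tf_edges) == 0L)) {
      g <- igraph::make_empty_graph(directed = TRUE)
    } else {
      g <- edges_to_igraph(edges, tf_edges)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back an edge TSV written by [export_network()]
#'
#' @param path Edge TSV path.
#' @return Edge data frame.
#' @export
read_edge_tsv <- function(path) {
  x <- read_tsv(path, c("mirna", "gene", "condition", "mirna_direction",
                        "level"))
  x$level <- as.integer(x$level)
  x
}
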