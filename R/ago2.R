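#' Ago2 IP-seq intersection
#'
#' RNA co-immunoprecipitated with Argonaute-2 enriches for RISC-loaded
#' miRNAs and their bound targets. Candidate MTI edges whose miRNA and gene
#' are both detected in the IP libraries above abundance floors (gene
#' FPKM >= 8, miRNA RPM >= 100) are promoted to evidence level 4; everything
#' else is dropped, so the IP step can only shrink a network.
#'
#' @name ago2
NULL

#' IP abundance filter
#'
#' @param min_gene_fpkm Gene floor in FPKM (default 8; genes below it in the
#'   IP library are filtered).
#' @param min_mirna_rpm miRNA floor in RPM (default 100).
#' @return A `glucomir_ip_filter` list.
#' @export
ip_filter <- function(min_gene_fpkm = 8, min_mirna_rpm = 100) {
  if (min_gene_fpkm < 0 || min_mirna_rpm < 0)
    stop("IP filter floors must be non-negative", call. = FALSE)
  structure(list(min_gene_fpkm = min_gene_fpkm,
                 min_mirna_rpm = min_mirna_rpm),
            class = "glucomir_ip_filter")
}

ip_values <- function(tab) {
  value_cols <- setdiff(names(tab), "id")
  vals <- as.matrix(tab[, value_cols, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0))
    stop("IP abundances must be non-negative and complete", call. = FALSE)
  apply(vals, 1L, max)
}

#' IP-supported entity sets
#'
#' An entity is supported when its IP abundance reaches the floor in any IP
#' library column (an entity exactly at the floor is retained: only values
#' strictly below it are filtered).
#'
#' @param gene_ip,mirna_ip Data frames with an `id` column and one or more
#'   abundance columns (single-condition tables as produced by
#'   [generate_ago2_tables()], or condition-split tables).
#' @param filter An [ip_filter()].
#' @return List `genes`, `mirnas` of supported id vectors.
#' @export
ip_supported_entities <- function(gene_ip, mirna_ip, filter = ip_filter()) {
  stopifnot(inherits(filter, "glucomir_ip_filter"))
  list(
    genes = gene_ip$id[ip_values(gene_ip) >= filter$min_gene_fpkm],
    mirnas = mirna_ip$id[ip_values(mirna_ip) >= filter$min_mirna_rpm]
  )
}

#' Promote IP-validated edges to level 4
#'
#' Returns the subset of edges whose miRNA and gene are both IP-supported,
#' with the evidence level overwritten to 4. The output is always a subset
#' of the input. The per-sub-network reduction ratio (edges out / edges in)
#' is attached as the `"reduction"` attribute.
#'
#' @param edges MTI edge data frame.
#' @param supported List `genes`, `mirnas` from [ip_supported_entities()].
#' @return Level-4 edge data frame (attribute `"reduction"`: data frame
#'   `network`, `n_in`, `n_out`, `ratio`).
#' @export
promote_level4 <- function(edges, supported) {
  keep <- edges$mirna %in% supported$mirnas & edges$gene %in% supported$genes
  out <- edges[keep, , drop = FALSE]
  if (nrow(out)) out$level <- 4L
  rownames(out) <- NULL
  nets_in <- split_networks(edges)$summary
  nets_out <- split_networks(out)$summary
  reduction <- data.frame(
    network = nets_in$network,
    n_in = nets_in$n_edges,
    n_out = nets_out$n_edges,
    ratio = ifelse(nets_in$n_edges > 0,
                   nets_out$n_edges / nets_in$n_edges, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "reduction") <- reduction
  out
}
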