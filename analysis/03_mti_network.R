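#!/usr/bin/env Rscript

# Stage 3 - evidence resolution and inverse-expression network.
#
# Merges experimental MTIs with the four prediction tables, applies the
# consensus rule (>= 3 tools, MFE <= -10 kcal/mol, miRanda score >= 140),
# resolves evidence levels 1-3, pairs DE miRNAs with inverse-profile DE
# genes per condition, overlays the TF layer, and exports the networks
# under results/network/.

suppressPackageStartupMessages(library(glucomir))

dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
tools <- c("miranda", "pita", "targetscan", "rnahybrid")
experimental <- load_experimental("results/inputs/mti_experimental.tsv")
predictions <- load_predictions(as.list(setNames(
  sprintf("results/inputs/predictions_%s.tsv", tools), tools)))
evidence <- resolve_evidence(merge_evidence(experimental, predictions))
write.table(evidence, "results/network/evidence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Evidence candidates resolved to levels 1-3:", nrow(evidence),
    "(", paste(names(table(evidence$level)), table(evidence$level),
               sep = ": L", collapse = ", "), ")\n")

gene_profiles <- read.delim("results/de/gene_profiles.tsv")
mirna_profiles <- read.delim("results/de/mirna_profiles.tsv")
edges <- build_mti_edges(mirna_profiles, gene_profiles, evidence)
nets <- split_networks(edges)
export_network(edges, "results/network/network_edges.tsv", "edge-tsv")
export_network(edges, "results/network/network.sif", "sif")

tf_table <- read_tf_table("results/inputs/tf_mirna.tsv")
tf_edges <- build_tf_layer(tf_table, gene_profiles, mirna_profiles)
write.table(tf_edges, "results/network/tf_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
export_network(edges, "results/network/network.graphml", "graphml",
               tf_edges = tf_edges)
write.table(nets$summary, "results/network/network_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("MTI edges:", nrow(edges), "across the four sub-networks:\n")
print(nets$summary)
cat("TF-miRNA edges retained:", nrow(tf_edges), "from",
    nrow(tf_table), "table rows\n")
for (nm in c("high_dn", "high_up", "low_dn", "low_up")) {
  hubs <- hub_mirnas(nets[[nm]], min_targets = 10)
  if (nrow(hubs))
    cat("Hub miRNAs in", nm, ":",
        paste(hubs$mirna, paste0("(", hubs$n_targets, ")"),
              collapse = ", "), "\n")
}
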