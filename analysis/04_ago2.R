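#!/usr/bin/env Rscript

# Stage 4 - Ago2 IP-seq intersection.
#
# Filters the IP abundance tables (gene FPKM >= 8, miRNA RPM >= 100),
# promotes candidate edges whose miRNA and gene are both IP-detected to
# evidence level 4, and reports the reduction per sub-network under
# results/ago2/.

suppressPackageStartupMessages(library(glucomir))

dir.create("results/ago2", recursive = TRUE, showWarnings = FALSE)
gene_ip <- read.delim("results/inputs/ago2_gene_ip.tsv")
mirna_ip <- read.delim("results/inputs/ago2_mirna_ip.tsv")
edges <- read_edge_tsv("results/network/network_edges.tsv")

supported <- ip_supported_entities(gene_ip, mirna_ip, ip_filter())
cat("IP-supported entities:", length(supported$genes), "genes,",
    length(supported$mirnas), "miRNAs\n")

level4 <- promote_level4(edges, supported)
export_network(level4, "results/ago2/level4_edges.tsv", "edge-tsv")
reduction <- attr(level4, "reduction")
write.table(reduction, "results/ago2/reduction.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Level-4 edges:", nrow(level4), "of", nrow(edges),
    "candidates; reduction per sub-network:\n")
print(reduction)
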