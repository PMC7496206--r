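#!/usr/bin/env Rscript

# Stage 5 - keyword sub-networks and functional enrichment.
#
# Carves the network into the G/O/E/C keyword sub-networks
# (glucose/carbon/insulin; ion/calcium; exocytosis/homeostasis;
# CREB/cAMP/transcription factor) and runs the exact hypergeometric
# over-representation test of the network gene set against the annotation
# term sets, with BH correction, under results/enrichment/.

suppressPackageStartupMessages(library(glucomir))

dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)
edges <- read_edge_tsv("results/network/network_edges.tsv")
annotations <- read_annotations("results/inputs/gene_annotations.tsv")
gene_profiles <- read.delim("results/de/gene_profiles.tsv")

nets <- keyword_networks(edges, annotations)
for (cat_name in names(nets)) {
  export_network(nets[[cat_name]],
                 sprintf("results/enrichment/network_%s_edges.tsv",
                         cat_name), "edge-tsv")
}
cat("Keyword sub-network edges - ",
    paste(names(nets), vapply(nets, nrow, 0L), sep = ": ",
          collapse = ", "), "\n")

# background: genes passing the abundance filters; query: network targets
terms <- annotation_terms(annotations)
all_terms <- sort(unique(unlist(terms)))
term_sets <- setNames(lapply(all_terms, function(t)
  names(terms)[vapply(terms, function(v) t %in% v, TRUE)]), all_terms)
# empty note fields round-trip as NA through read.delim
keep <- is.na(gene_profiles$note) | gene_profiles$note != "filtered_both"
background <- gene_profiles$entity[keep]
query <- intersect(unique(edges$gene), background)
res <- enrich(query, term_sets, background, correction = "bh", top = 20)
write.table(res, "results/enrichment/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Tested", length(term_sets), "terms over a", length(background),
    "-gene background; top terms:\n")
print(head(res, 5))
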