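#!/usr/bin/env Rscript

# Stage 2 - differential expression and profile classification.
#
# Calls up/down/nc per entity for the low-vs-moderate and high-vs-moderate
# comparisons (genes: fold change >= 1.5 / <= 0.67, FPKM floor 10; miRNAs:
# >= 1.4 / <= 0.71, RPM floor 10), classifies each entity into the nine
# glucose-response profile classes, and writes calls, profiles, and type
# counts under results/de/.

suppressPackageStartupMessages(library(glucomir))

dir.create("results/de", recursive = TRUE, showWarnings = FALSE)
gene_expr <- read_expression("results/inputs/gene_expression.tsv")
mirna_expr <- read_expression("results/inputs/mirna_expression.tsv")

stage <- function(expr, th, label) {
  low <- call_differential(expr, th, "low_vs_mod")
  high <- call_differential(expr, th, "high_vs_mod")
  profiles <- classify_entities(low, high)
  write.table(rbind(low, high),
              file.path("results/de", paste0(label, "_calls.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(profiles,
              file.path("results/de", paste0(label, "_profiles.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  profiles
}

gene_profiles <- stage(gene_expr, gene_thresholds(), "gene")
mirna_profiles <- stage(mirna_expr, mirna_thresholds(), "mirna")

tc <- data.frame(profile = PROFILE_TYPES,
                 genes = type_counts(gene_profiles),
                 mirnas = type_counts(mirna_profiles), row.names = NULL)
write.table(tc, "results/de/type_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("DE genes:", sum(gene_profiles$profile != "FLAT"), "of",
    nrow(gene_profiles), "; DE miRNAs:",
    sum(mirna_profiles$profile != "FLAT"), "of", nrow(mirna_profiles), "\n")
print(tc)
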