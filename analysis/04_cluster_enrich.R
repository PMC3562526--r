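#!/usr/bin/env Rscript
# Downstream of the DE call: chord-distance complete-linkage clustering of
# the DE probe-sets' log2 expression profiles (cut at k = 8), Wilcoxon
# functional-bin enrichment of the fold changes, and a three-"species"
# comparison of up-regulated gene sets across independently simulated
# studies sharing the gene-identifier namespace.

suppressPackageStartupMessages(library(xspecies))

ds <- read_dataset("results/data")
expr <- read_expression_matrix("results/expression.tsv")
de <- read_de_table("results/de_table.tsv")

sel <- de$probe_set_id[de$selected]
cl <- hcluster(unclass(expr)[sel, , drop = FALSE], k = 8)
write.table(data.frame(probe_set_id = cl$probe_set_ids, cluster = cl$labels),
            "results/clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("clustered %d DE probe-sets into %d clusters (sizes: %s)",
                length(sel), cl$k, paste(tabulate(cl$labels, 8), collapse = ", ")))

fc <- setNames(de$log2fc, de$probe_set_id)
enr <- wilcoxon_bin_enrichment(fc, ds$annotation)
write.table(enr, "results/bin_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- enr[order(enr$p_adj), ][1, ]
message(sprintf("most enriched bin: %s (%s, adjusted p = %.3g)",
                top$bin, top$direction, top$p_adj))

# cross-platform comparison: three noisy measurements of the same biology
# (this study's fold changes plus two platforms with independent measurement
# noise, sd 0.25), matched by gene identifier; up-sets at log2 threshold 0.3
set.seed(77)
genes <- ds$annotation$gene_id[match(de$probe_set_id, ds$annotation$probe_set_id)]
base_fc <- setNames(de$log2fc, genes)
tables <- list(platform_a = base_fc,
               platform_b = base_fc + rnorm(length(base_fc), 0, 0.25),
               platform_c = base_fc + rnorm(length(base_fc), 0, 0.25))
venn <- compare_up_sets(tables, log2_threshold = 0.3)
write.table(venn, "results/up_set_venn.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("up-set overlap (log2 >= 0.3): %d genes called up on all three platforms; exclusives %d / %d / %d",
                venn$count[venn$region == "platform_a&platform_b&platform_c"],
                venn$count[venn$region == "platform_a"],
                venn$count[venn$region == "platform_b"],
                venn$count[venn$region == "platform_c"]))
message("clusters, enrichment and Venn tables written under results/")
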