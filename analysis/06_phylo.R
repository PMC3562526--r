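#!/usr/bin/env Rscript
# Comparative stage: p-distances and a neighbor-joining tree from a small
# synthetic aligned protein family (five fleshy-fruit "orthologs" diverged in
# code from one ancestral sequence), written as Newick.

suppressPackageStartupMessages(library(xspecies))
set.seed(66)

aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
len <- 120
ancestor <- sample(aa, len, replace = TRUE)
mutate <- function(seq, p) {
  hit <- runif(len) < p
  seq[hit] <- sample(aa, sum(hit), replace = TRUE)
  seq
}
seqs <- rbind(
  papaya = mutate(ancestor, 0.05),
  tomato = mutate(ancestor, 0.15),
  grape = mutate(ancestor, 0.20),
  apple = mutate(ancestor, 0.25),
  arabidopsis = mutate(ancestor, 0.35)
)
seqs[2, 3:6] <- "-"  # a small indel region, exercising pairwise deletion
aln <- as_alignment(seqs)

dm <- p_distance_matrix(aln)
write.table(round(dm, 4), "results/p_distances.tsv", sep = "\t", quote = FALSE)

tree <- neighbor_joining(dm)
write_newick(tree, "results/family_tree.nwk")
message("p-distance range: ", sprintf("%.3f-%.3f", min(dm[dm > 0]), max(dm)))
message("NJ tree: ", readLines("results/family_tree.nwk"))
message("distance matrix and Newick tree written under results/")
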