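#!/usr/bin/env Rscript
# Generate the synthetic cross-species study: one papaya-like gDNA
# hybridization of a heterologous 1000-probe-set chip plus a triplicate of
# RNA hybridizations per ripening stage, with 50% probe divergence, heavy
# attenuation of diverged probes, and 10% planted differential expression.
# Writes the dataset (with ground truth) under results/data/.

suppressPackageStartupMessages(library(xspecies))

cfg <- sim_config(divergence_fraction = 0.5, attenuation = 0.05,
                  de_fraction = 0.1, de_log2fc = 1, noise_sd = 0.2, seed = 7)
ds <- simulate_dataset(cfg)
manifest <- write_dataset(ds, "results/data", overwrite = TRUE)

n_div <- length(ds$truth$diverged_probes)
n_de <- sum(ds$truth$de_sets != 0)
message(sprintf("simulated %d probe-sets x %d pairs: %d diverged probes (%.0f%%), %d DE sets (half up, half down)",
                cfg$n_probe_sets, cfg$pairs_per_set, n_div,
                100 * n_div / (cfg$n_probe_sets * cfg$pairs_per_set), n_de))
message("dataset written to results/data (manifest: ", manifest, ")")
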