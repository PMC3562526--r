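# Shared fixtures built in code.

# Two probe-sets (3 + 2 pairs); PM indices 0..4.
tiny_layout <- function() {
  chip_layout(
    probe_set_id = c("PS1", "PS1", "PS1", "PS2", "PS2"),
    pair_rank = c(1L, 2L, 3L, 1L, 2L),
    pm_index = 0:4,
    mm_index = 5:9
  )
}

# gDNA table over tiny_layout() with the worked masking intensities:
# PS1 pairs {80, 60, 90}, PS2 pairs {70, 50}.
tiny_gdna <- function() {
  probe_intensities("g1", "gdna", "",
                    stats::setNames(c(80, 60, 90, 70, 50), as.character(0:4)))
}

# A small but fully featured simulated dataset, cached per test run.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_probe_sets = 120, seed = 101))
    }
    cache
  }
})

random_layout <- function(n_sets, pairs, seed) {
  set.seed(seed)
  chip_layout(
    probe_set_id = rep(sprintf("S%03d", seq_len(n_sets)), each = pairs),
    pair_rank = rep(seq_len(pairs), n_sets),
    pm_index = sample.int(n_sets * pairs * 2, n_sets * pairs) - 1L
  )
}

random_gdna <- function(layout, seed, max_intensity = 500) {
  set.seed(seed)
  probe_intensities(
    paste0("g", seed), "gdna", "",
    stats::setNames(stats::runif(nrow(layout), 0, max_intensity),
                    as.character(layout$pm_index)))
}

# Brute-force mask: literal application of the retention rule, independent of
# build_mask's vectorized path.
brute_force_mask <- function(gdna, layout, threshold) {
  mean_sig <- rowMeans(sapply(gdna, function(g) {
    g$intensities[as.character(layout$pm_index)]
  }))
  retained_pairs <- list()
  for (s in probe_set_ids(layout)) {
    rows <- which(layout$probe_set_id == s)
    kept <- integer()
    for (r in rows) if (mean_sig[r] > threshold) kept <- c(kept, layout$pair_rank[r])
    retained_pairs[[s]] <- kept
  }
  retained_sets <- names(retained_pairs)[vapply(retained_pairs, length, 0L) >= 2]
  list(retained_pairs = retained_pairs, retained_sets = retained_sets)
}
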