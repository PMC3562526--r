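# Synthetic cross-species hybridization generator.
#
# Emulates the study design behind gDNA-based probe masking: one (or more)
# genomic-DNA hybridizations of the target species on a heterologous chip,
# plus replicated RNA hybridizations for two ripening stages, with known
# probe-level sequence divergence and planted differential expression so
# every downstream stage has ground truth.

#' Simulation configuration
#'
#' Defaults describe an ATH1-like design: 11 probe-pairs per probe-set and a
#' triplicate of RNA hybridizations per fruit stage (unripe, ripe). Signals
#' are generated on the log2 scale: probe affinity `a_i ~ Normal(0, 0.5 sd)`,
#' probe-set abundance `mu_s ~ Normal(0, 1)`, additive Gaussian noise with sd
#' `noise_sd`. A probe is "diverged" (cross-species mismatch) with probability
#' `divergence_fraction`; diverged probes have their linear-scale binding
#' multiplied by `attenuation` in both gDNA and RNA hybridizations, the shared
#' sequence property that gDNA masking exploits. A fraction `de_fraction` of
#' probe-sets carries a planted log2 fold change of magnitude `de_log2fc`
#' (half up-, half down-regulated in the ripe stage).
#'
#' Every measured intensity is hybridization signal plus optical background,
#' `X = S + B` with `B ~ Normal(optical_bg_mean, optical_bg_sd)` truncated at
#' zero and drawn fresh per probe per array — the additive component the RMA
#' background-correction model assumes. The background is what makes weakly
#' hybridizing (diverged) probes uninformative: once the attenuated signal
#' falls below the background level the fold change is no longer measurable
#' on that probe, which is the premise of gDNA-based masking. Setting both
#' background parameters to 0 gives the noiseless limiting model in which the
#' log2 PM intensity is exactly `baseline_log2 + mu_s + delta_s + a_i`.
#'
#' @param n_probe_sets number of probe-sets on the chip.
#' @param pairs_per_set probe-pairs per probe-set (>= 2).
#' @param n_reps RNA replicate arrays per condition (>= 2).
#' @param n_gdna number of gDNA hybridization arrays (>= 1).
#' @param divergence_fraction probability a probe is diverged, in [0, 1].
#' @param attenuation linear-scale binding multiplier for diverged probes,
#'   in (0, 1].
#' @param de_fraction fraction of probe-sets with planted DE, in [0, 1].
#' @param de_log2fc magnitude of the planted log2 fold change.
#' @param noise_sd sd of additive Gaussian noise on the log2 scale.
#' @param baseline_log2 mean log2 abundance of RNA signal.
#' @param gdna_level mean log2 gDNA signal of a non-diverged probe.
#' @param optical_bg_mean mean of the additive optical background (linear
#'   fluorescence units).
#' @param optical_bg_sd sd of the additive optical background.
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   bit-identically.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probe_sets = 1000, pairs_per_set = 11, n_reps = 3,
                       n_gdna = 1, divergence_fraction = 0.4, attenuation = 0.1,
                       de_fraction = 0.1, de_log2fc = 1, noise_sd = 0.2,
                       baseline_log2 = 8, gdna_level = 8,
                       optical_bg_mean = 50, optical_bg_sd = 15, seed = 1) {
  cfg <- list(n_probe_sets = as.integer(n_probe_sets),
              pairs_per_set = as.integer(pairs_per_set),
              n_reps = as.integer(n_reps), n_gdna = as.integer(n_gdna),
              divergence_fraction = divergence_fraction,
              attenuation = attenuation, de_fraction = de_fraction,
              de_log2fc = de_log2fc, noise_sd = noise_sd,
              baseline_log2 = baseline_log2, gdna_level = gdna_level,
              optical_bg_mean = optical_bg_mean, optical_bg_sd = optical_bg_sd,
              seed = as.integer(seed))
  ok <- cfg$n_probe_sets >= 1 && cfg$pairs_per_set >= 2 && cfg$n_reps >= 2 &&
    cfg$n_gdna >= 1 &&
    cfg$divergence_fraction >= 0 && cfg$divergence_fraction <= 1 &&
    cfg$attenuation > 0 && cfg$attenuation <= 1 &&
    cfg$de_fraction >= 0 && cfg$de_fraction <= 1 && cfg$noise_sd >= 0 &&
    cfg$optical_bg_mean >= 0 && cfg$optical_bg_sd >= 0
  if (!ok) stop("invalid simulation configuration", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a cross-species hybridization dataset
#'
#' Generative model, per probe i of probe-set s: binding factor
#' `b_i = attenuation` if probe i is diverged else 1;
#' gDNA signal `= 2^(gdna_level + a_i + eps) * b_i`; RNA signal on an array of
#' condition c `= 2^(baseline_log2 + mu_s + delta_s * 1[c == "ripe"] + a_i +
#' eps) * b_i`, with `eps ~ Normal(0, noise_sd)` drawn per probe per array and
#' probe affinities `a_i` shared across arrays (affinity is a sequence
#' property; median polish absorbs it). A truncated-normal optical background
#' is then added to every measurement (see [sim_config()]).
#'
#' @param config a [sim_config()].
#' @return A `sim_dataset` list with elements `layout` (a [chip_layout()]),
#'   `gdna` and `rna` (lists of [probe_intensities()]), `truth` (list with
#'   `diverged_probes`, integer PM indices, and `de_sets`, named numeric of
#'   true log2 fold changes, 0 for non-DE), `annotation` (an annotation map
#'   in which bin `RIPENING` collects the up-regulated DE sets, the positive
#'   control for enrichment), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ns <- config$n_probe_sets
  np <- config$pairs_per_set
  n_probes <- ns * np
  set_ids <- sprintf("PS%05d", seq_len(ns))
  layout <- chip_layout(
    probe_set_id = rep(set_ids, each = np),
    pair_rank = rep(seq_len(np), times = ns),
    pm_index = seq_len(n_probes) - 1L,
    mm_index = seq_len(n_probes) - 1L + n_probes,
    chip_name = sprintf("SYNTH-%d", config$seed)
  )
  pm_names <- as.character(layout$pm_index)

  affinity <- stats::rnorm(n_probes, 0, 0.5)
  diverged <- stats::runif(n_probes) < config$divergence_fraction
  b <- ifelse(diverged, config$attenuation, 1)
  mu <- stats::rnorm(ns, 0, 1)

  n_de <- round(config$de_fraction * ns)
  delta <- stats::setNames(numeric(ns), set_ids)
  if (n_de > 0) {
    de_idx <- sample.int(ns, n_de)
    sign <- rep(c(1, -1), length.out = n_de)
    delta[de_idx] <- sign * config$de_log2fc
  }
  set_of_probe <- rep(seq_len(ns), each = np)

  optical_bg <- function() {
    if (config$optical_bg_mean == 0 && config$optical_bg_sd == 0) return(0)
    pmax(stats::rnorm(n_probes, config$optical_bg_mean, config$optical_bg_sd), 0)
  }
  gdna <- lapply(seq_len(config$n_gdna), function(g) {
    eps <- stats::rnorm(n_probes, 0, config$noise_sd)
    sig <- 2^(config$gdna_level + affinity + eps) * b + optical_bg()
    probe_intensities(sprintf("gdna_%d", g), "gdna", "",
                      stats::setNames(sig, pm_names))
  })

  rna <- list()
  for (cond in c("unripe", "ripe")) {
    shift <- if (cond == "ripe") delta[set_of_probe] else 0
    for (r in seq_len(config$n_reps)) {
      eps <- stats::rnorm(n_probes, 0, config$noise_sd)
      sig <- 2^(config$baseline_log2 + mu[set_of_probe] + shift +
                  affinity + eps) * b + optical_bg()
      rna[[length(rna) + 1L]] <- probe_intensities(
        sprintf("rna_%s_%d", cond, r), "rna", cond,
        stats::setNames(sig, pm_names))
    }
  }

  annotation <- synth_annotation(set_ids, delta)
  structure(list(layout = layout, gdna = gdna, rna = rna,
                 truth = list(diverged_probes = layout$pm_index[diverged],
                              de_sets = delta),
                 annotation = annotation, config = config),
            class = "sim_dataset")
}

# Bin assignment: up-regulated DE sets all carry bin RIPENING (the planted
# enrichment), every set also gets one background bin drawn round-robin so
# bins are deterministic given the set order.
synth_annotation <- function(set_ids, delta) {
  background <- sprintf("BIN%02d", (seq_along(set_ids) - 1L) %% 10L + 1L)
  bins <- ifelse(delta[set_ids] > 0, paste("RIPENING", background, sep = ";"),
                 background)
  df <- data.frame(probe_set_id = set_ids,
                   gene_id = sprintf("AT%05dG", seq_along(set_ids)),
                   bins = bins, go = "", stringsAsFactors = FALSE)
  class(df) <- c("annotation_map", "data.frame")
  df
}

#' Write a simulated dataset to a directory
#'
#' Writes the layout, every intensity table, the annotation map, the ground
#' truth (`truth.tsv`: probe-set, true log2fc; `diverged_probes.tsv`), and a
#' JSON manifest recording the file list, configuration and seed.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory.
#' @param overwrite refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stop("directory ", dir, " is non-empty; use overwrite = TRUE", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  write_layout(dataset$layout, file.path(dir, "layout.tsv"))
  files <- c(files, "layout.tsv")
  for (tab in c(dataset$gdna, dataset$rna)) {
    f <- paste0(tab$array_id, ".tsv")
    write_intensities(tab, file.path(dir, f))
    files <- c(files, f)
  }
  write_annotation(dataset$annotation, file.path(dir, "annotation.tsv"))
  utils::write.table(
    data.frame(probe_set_id = names(dataset$truth$de_sets),
               true_log2fc = format(dataset$truth$de_sets, digits = 15, trim = TRUE)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(pm_index = dataset$truth$diverged_probes),
    file.path(dir, "diverged_probes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "annotation.tsv", "truth.tsv", "diverged_probes.tsv")
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(files = files, config = unclass(dataset$config),
         seed = dataset$config$seed),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a simulated dataset back from a directory
#' @param dir directory written by [write_dataset()].
#' @return A `sim_dataset` (ground truth included).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  layout <- read_layout(file.path(dir, "layout.tsv"), contiguous_ranks = TRUE)
  tabs <- lapply(grep("^(gdna|rna)_", manifest$files, value = TRUE),
                 function(f) read_intensities(file.path(dir, f), layout))
  kinds <- vapply(tabs, `[[`, "", "kind")
  truth <- utils::read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  div <- utils::read.delim(file.path(dir, "diverged_probes.tsv"))
  structure(list(
    layout = layout,
    gdna = tabs[kinds == "gdna"],
    rna = tabs[kinds == "rna"],
    truth = list(diverged_probes = div$pm_index,
                 de_sets = stats::setNames(truth$true_log2fc, truth$probe_set_id)),
    annotation = read_annotation(file.path(dir, "annotation.tsv")),
    config = do.call(sim_config, manifest$config)
  ), class = "sim_dataset")
}
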