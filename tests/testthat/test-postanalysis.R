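test_that("chord distance matches its closed forms", {
  expect_equal(chord_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(chord_distance(c(2, 0), c(1, 0)), 0)
  expect_equal(chord_distance(c(1, 1), c(1, 0)), sqrt(2 - sqrt(2)),
               tolerance = 1e-12)
  expect_equal(chord_distance(c(1, 1), c(1, 0)), 0.76537, tolerance = 1e-5)
  expect_error(chord_distance(c(0, 0), c(1, 0)), "zero vector")
  expect_error(chord_distance(1:2, 1:3), "equal length")
})

test_that("chord distance equals sqrt(2 - 2 cos theta) on random pairs", {
  set.seed(23)
  for (k in 1:200) {
    x <- stats::rnorm(6); y <- stats::rnorm(6)
    ct <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    expect_equal(chord_distance(x, y), sqrt(max(0, 2 - 2 * ct)),
                 tolerance = 1e-12)
  }
})

test_that("complete-linkage chord clustering separates opposite profiles", {
  set.seed(24)
  up <- t(replicate(10, c(1, 1, 1, 3, 3, 3) + stats::rnorm(6, 0, 1e-9)))
  down <- t(replicate(8, c(3, 3, 3, 1, 1, 1) + stats::rnorm(6, 0, 1e-9)))
  rows <- rbind(up, down)
  rownames(rows) <- sprintf("P%02d", 1:18)
  cl <- hcluster(rows, k = 2)
  expect_length(unique(cl$labels[1:10]), 1)
  expect_length(unique(cl$labels[11:18]), 1)
  expect_false(cl$labels[1] == cl$labels[11])

  # merge heights are monotone under complete linkage
  expect_true(all(diff(cl$heights) >= -1e-12))

  expect_equal(max(hcluster(rows, k = 1)$labels), 1)
  expect_equal(sort(unique(hcluster(rows, k = 18)$labels)), 1:18)
  expect_error(hcluster(rows, k = 19), "k must lie")
})

test_that("direction partition splits the selected sets exactly", {
  de <- data.frame(
    probe_set_id = c("FRUCT", "PL", "X1", "X2"),
    log2fc = c(1.738, -1.228, 0.1, 2),
    p_raw = c(0.0358, 0.0408, 0.9, 0.2),
    p_adj = c(0.04, 0.05, 0.95, 0.3),
    direction = c("up", "down", "flat", "flat"),
    selected = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  parts <- partition_direction(de)
  expect_identical(parts$up, "FRUCT")
  expect_identical(parts$down, "PL")
  expect_length(intersect(parts$up, parts$down), 0)
  expect_setequal(c(parts$up, parts$down), de$probe_set_id[de$selected])

  none <- partition_direction(de[!de$selected, ])
  expect_length(none$up, 0)
  expect_length(none$down, 0)
})

test_that("bin enrichment reproduces the exact 3-vs-4 rank-sum p-value", {
  log2fc <- stats::setNames(c(2.0, 1.8, 1.5, 0.1, -0.2, 0.0, 0.2),
                            paste0("P", 1:7))
  annot <- data.frame(probe_set_id = paste0("P", 1:7),
                      gene_id = paste0("G", 1:7),
                      bins = c(rep("HOT", 3), rep("BG", 4)), go = "",
                      stringsAsFactors = FALSE)
  res <- wilcoxon_bin_enrichment(log2fc, annot, min_bin_size = 3)
  hot <- res[res$bin == "HOT", ]
  expect_equal(hot$p_raw, 2 / 35, tolerance = 1e-12)
  expect_identical(hot$direction, "up")

  # swapping member and non-member labels flips direction, preserves p
  bg <- res[res$bin == "BG", ]
  expect_equal(bg$p_raw, hot$p_raw, tolerance = 1e-12)
  expect_identical(bg$direction, "down")
})

test_that("exact and normal-approximation enrichment p-values agree at the boundary", {
  set.seed(26)
  members <- stats::rnorm(8, 1, 1)
  others <- stats::rnorm(30, 0, 1)
  exact_p <- stats::wilcox.test(members, others, exact = TRUE)$p.value
  approx_p <- stats::wilcox.test(members, others, exact = FALSE,
                                 correct = TRUE)$p.value
  expect_lt(abs(exact_p - approx_p), 0.02)
})

test_that("enrichment rejects degenerate annotations", {
  log2fc <- stats::setNames(stats::rnorm(5), paste0("P", 1:5))
  all_one <- data.frame(probe_set_id = paste0("P", 1:5),
                        gene_id = paste0("G", 1:5), bins = "ONLY", go = "",
                        stringsAsFactors = FALSE)
  expect_error(wilcoxon_bin_enrichment(log2fc, all_one), "every scored gene")
  tiny <- all_one
  tiny$bins <- c("A", "A", "B", "B", "B")
  expect_error(wilcoxon_bin_enrichment(log2fc, tiny, min_bin_size = 4),
               "no annotated bin")
})

test_that("the planted RIPENING bin is detected as enriched in simulation", {
  ds <- small_dataset()
  pipe <- masked_de_pipeline(ds, 75)
  fc <- stats::setNames(pipe$de$log2fc, pipe$de$probe_set_id)
  res <- wilcoxon_bin_enrichment(fc, ds$annotation)
  rip <- res[res$bin == "RIPENING", ]
  expect_identical(rip$direction, "up")
  expect_lt(rip$p_adj, 0.01)
})

test_that("up-set comparison counts Venn cells from construction", {
  a <- stats::setNames(c(1, 1, 1, 0.1, -1), paste0("G", 1:5))
  expect_warning(
    disjoint <- compare_up_sets(list(s1 = a,
                                     s2 = stats::setNames(rep(1, 3), paste0("H", 1:3)))),
    "shared across"
  )
  expect_equal(disjoint$count[disjoint$region == "s1&s2"], 0)

  same <- compare_up_sets(list(x = a, y = a), log2_threshold = 0.3)
  expect_equal(same$count[same$region == "x&y"], 3)
  expect_equal(same$count[same$region %in% c("x", "y")], c(0, 0))

  # three platforms with a constructed Venn: 10 shared by all, 4 in p&t,
  # 3 exclusive to p, 2 to t, 5 to g
  shared <- paste0("S", 1:10)
  pt <- paste0("PT", 1:4)
  p_only <- paste0("P", 1:3); t_only <- paste0("T", 1:2); g_only <- paste0("G", 1:5)
  mk <- function(ids) stats::setNames(rep(1, length(ids)), ids)
  venn <- compare_up_sets(list(
    papaya = mk(c(shared, pt, p_only)),
    tomato = mk(c(shared, pt, t_only)),
    grape = mk(c(shared, g_only))
  ), log2_threshold = 0.3)
  get <- function(region) venn$count[venn$region == region]
  expect_equal(get("papaya&tomato&grape"), 10)
  expect_equal(get("papaya&tomato"), 4)
  expect_equal(get("papaya"), 3)
  expect_equal(get("tomato"), 2)
  expect_equal(get("grape"), 5)
  expect_equal(get("papaya&grape"), 0)
})
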