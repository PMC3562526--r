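test_that("standard-curve fits recover exact lines and efficiencies", {
  x <- -4:0
  perfect <- data.frame(log10_quantity = x, ct = -1 / log10(2) * x + 20)
  curve <- fit_standard_curve(perfect)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)  # 100% per cycle
  expect_equal(curve$r2, 1, tolerance = 1e-12)

  line <- data.frame(log10_quantity = x, ct = -3 * x + 20)
  fit <- fit_standard_curve(line)
  expect_equal(fit$slope, -3, tolerance = 1e-12)
  expect_equal(fit$intercept, 20, tolerance = 1e-12)

  expect_error(fit_standard_curve(perfect[1:2, ]), ">= 3 distinct")
  expect_error(fit_standard_curve(data.frame(log10_quantity = c(1, 1, 1),
                                             ct = 1:3)), ">= 3 distinct")
})

test_that("noisy dilution series still recover the slope", {
  set.seed(27)
  x <- rep(-4:0, each = 4)
  noisy <- data.frame(log10_quantity = x, ct = -3.4 * x + 18 + stats::rnorm(20, 0, 0.2))
  fit <- fit_standard_curve(noisy)
  expect_lt(abs(fit$slope + 3.4), 0.15)
})

test_that("quantification inverts the standard curve", {
  curve <- fit_standard_curve(data.frame(log10_quantity = -3:0, ct = -3.2 * (-3:0) + 21))
  expect_equal(quantify(curve$intercept, curve), 1, tolerance = 1e-12)
  expect_equal(quantify(curve$intercept + curve$slope, curve), 10,
               tolerance = 1e-12)
  # fit-then-quantify is the identity on a noiseless series
  expect_equal(quantify(-3.2 * (-3:0) + 21, curve), 10^(-3:0), tolerance = 1e-9)

  up <- curve; up$slope <- 3.2
  expect_error(quantify(20, up), "negative")
})

test_that("technical replicates are averaged at the Ct level", {
  meas <- data.frame(gene = "g", sample = rep(c("d1", "d2"), each = 4),
                     replicate = rep(1:4, 2),
                     ct = c(20, 20.2, 19.8, 20, 18, 18.1, 17.9, 18))
  avg <- average_ct(meas)
  expect_equal(avg$ct[avg$sample == "d1"], 20)
  expect_equal(avg$ct[avg$sample == "d2"], 18)
  expect_error(average_ct(meas[c(1, 5), ]), ">= 2 technical")
  expect_error(average_ct(transform(meas, ct = -ct)), "> 0")
})

test_that("relative expression normalizes by the geometric reference mean", {
  target <- c(d1 = 4, d2 = 16)
  refs <- list(actin = c(d1 = 2, d2 = 8), r18S = c(d1 = 8, d2 = 2))
  rel <- relative_expression(target, refs, calibrator = "d1")
  # divisor sqrt(2*8) = 4 for both samples -> normalized (1, 4)
  expect_identical(unname(rel["d1"]), 1)
  expect_equal(unname(rel["d2"]), 4)

  # one constant reference: relative values proportional to target quantities
  rel2 <- relative_expression(target, list(actin = c(d1 = 5, d2 = 5)), "d1")
  expect_equal(unname(rel2), unname(target / target["d1"]))

  # invariant to rescaling any one gene's quantities
  rel3 <- relative_expression(target * 37,
                              list(actin = refs$actin, r18S = refs$r18S * 0.01),
                              "d1")
  expect_equal(rel3, rel, tolerance = 1e-12)

  expect_error(relative_expression(target, list(a = c(d1 = 0, d2 = 1)), "d1"),
               "> 0")
  expect_error(relative_expression(target, refs, "d9"), "calibrator")
})

test_that("ANOVA + Tukey flags match a hand studentized-range computation", {
  # 3 balanced groups, n = 4 each, df = 9; published q(0.05; 3, 9) = 3.948
  # d2 sits 0.05 above the calibrator, inside the HSD ~ 0.16; d3 far outside
  groups <- list(d1 = c(1.0, 1.1, 0.9, 1.0),
                 d2 = c(1.05, 1.15, 0.95, 1.05),
                 d3 = c(3.0, 3.1, 2.9, 3.0))
  res <- anova_tukey(groups, calibrator = "d1")
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / 9
  hsd <- 3.948 * sqrt(mse / 4)
  means <- vapply(groups, mean, 0)
  for (i in seq_len(nrow(res$tukey))) {
    d <- abs(means[res$tukey$group2[i]] - means[res$tukey$group1[i]])
    expect_identical(res$tukey$significant[i], unname(d > hsd))
  }
  expect_identical(unname(res$differs_from_calibrator), c(FALSE, TRUE))

  # symmetric in group order
  rev_res <- anova_tukey(rev(groups), calibrator = "d1")
  pair_key <- function(r) sort(paste(pmin(r$tukey$group1, r$tukey$group2),
                                     pmax(r$tukey$group1, r$tukey$group2)))
  expect_identical(pair_key(rev_res), pair_key(res))
  expect_equal(rev_res$p, res$p, tolerance = 1e-12)
  expect_identical(rev_res$differs_from_calibrator[names(res$differs_from_calibrator)],
                   res$differs_from_calibrator)
})

test_that("degenerate ANOVA inputs behave as expected", {
  same <- list(a = c(1, 1, 1, 1), b = c(1, 1, 1, 1))
  res <- anova_tukey(same, calibrator = "a")
  expect_false(any(res$differs_from_calibrator))

  sep <- list(a = c(1, 1.01, 0.99, 1), b = c(10, 10.01, 9.99, 10))
  expect_true(anova_tukey(sep, "a")$differs_from_calibrator[["b"]])

  expect_error(anova_tukey(list(a = 1, b = c(1, 2)), "a"), ">= 2 replicates")
  expect_error(anova_tukey(list(a = c(1, 2)), "a"), ">= 2 groups")
})
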