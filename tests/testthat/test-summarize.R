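# Independent oracle: posterior mean of the signal under X = S + B by direct
# numerical integration of the convolution density.
bg_posterior_mean_numeric <- function(x, mu, sigma, alpha) {
  num <- stats::integrate(function(s) s * exp(-alpha * s) *
                            stats::dnorm(x - s - mu, 0, sigma), 0, Inf,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(function(s) exp(-alpha * s) *
                            stats::dnorm(x - s - mu, 0, sigma), 0, Inf,
                          rel.tol = 1e-10)$value
  num / den
}

test_that("background correction matches the numerical posterior mean", {
  model <- background_model(mu = 100, sigma = 1, alpha = 1)
  xs <- seq(95, 114, by = 1)  # includes x = mu and both tails
  expected <- vapply(xs, bg_posterior_mean_numeric, 0,
                     mu = 100, sigma = 1, alpha = 1)
  expect_equal(background_correct(xs, model), expected, tolerance = 1e-6)
})

test_that("background correction has the stated limits and shape", {
  # sigma -> 0, alpha -> 0, x > mu: corrected -> x - mu
  model <- background_model(mu = 40, sigma = 1e-6, alpha = 1e-9)
  expect_equal(background_correct(100, model), 60, tolerance = 1e-5)

  model <- background_model(mu = 50, sigma = 20, alpha = 0.02)
  x <- seq(0, 400, by = 2)
  corrected <- background_correct(x, model)
  expect_true(all(corrected > 0))
  expect_true(all(diff(corrected) > 0))
  expect_error(background_correct(c(1, NA), model), "non-finite")
})

test_that("background estimation recovers known mixture parameters", {
  set.seed(5)
  x <- stats::rnorm(50000, 100, 10) + stats::rexp(50000, 0.01)
  m <- estimate_background(x)
  expect_lt(abs(m$mu - 100), 5)
  expect_lt(abs(m$alpha - 0.01), 0.003)

  m2 <- estimate_background(2 * x)
  expect_equal(m2$mu / m$mu, 2, tolerance = 0.1)
  expect_equal(m2$sigma / m$sigma, 2, tolerance = 0.1)

  expect_error(estimate_background(rep(7, 200)), "constant")
  expect_error(estimate_background(stats::runif(50)), ">= 100")
})

test_that("quantile normalization matches the sort-average-assign oracle", {
  m <- cbind(A = c(5, 2, 3), B = c(4, 1, 6))
  out <- quantile_normalize(m)
  expect_equal(out[, "A"], c(5.5, 1.5, 3.5), ignore_attr = TRUE)
  expect_equal(out[, "B"], c(3.5, 1.5, 5.5), ignore_attr = TRUE)

  # fixed point on identical columns; idempotent in general
  same <- cbind(a = c(1, 5, 2), b = c(1, 5, 2))
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)
  set.seed(8)
  r <- matrix(stats::rnorm(60), 15, 4)
  once <- quantile_normalize(r)
  expect_equal(quantile_normalize(once), once, tolerance = 1e-12)
  expect_equal(diff(range(colSums(once))), 0, tolerance = 1e-9)

  expect_warning(quantile_normalize(matrix(1:3, ncol = 1)), "no-op")
})

test_that("median polish reproduces the hand-worked example and its fixed points", {
  m <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(NULL, c("a1", "a2")))
  expr <- median_polish_summarize(m)
  expect_equal(unname(expr), c(2, 3))

  # additive matrix r_i + c_j is a fixed point: expression = overall + c_j
  r <- c(0.5, -1, 2); cc <- c(10, 11, 9, 12)
  add <- outer(r, cc, `+`)
  colnames(add) <- paste0("a", 1:4)
  expr_add <- median_polish_summarize(add)
  expect_equal(unname(diff(expr_add)), diff(cc), tolerance = 1e-10)

  # location equivariance
  expect_equal(median_polish_summarize(add + 0.37), expr_add + 0.37,
               tolerance = 1e-10)
})

test_that("median polish residuals have vanishing row and column medians", {
  # probe-set-shaped matrices (11 retained pairs x 6 arrays); with an odd
  # probe count the alternating sweeps reach a true fixed point
  set.seed(12)
  for (k in 1:20) {
    m <- matrix(stats::rnorm(66), 11, 6)
    fit <- suppressWarnings(stats::medpolish(m, eps = 1e-12, maxiter = 500L,
                                             trace.iter = FALSE))
    expect_lt(max(abs(apply(fit$residuals, 1, stats::median))), 1e-6)
    expect_lt(max(abs(apply(fit$residuals, 2, stats::median))), 1e-6)
  }
})

test_that("rma recovers planted effects exactly on noiseless data", {
  cfg <- sim_config(n_probe_sets = 40, divergence_fraction = 0, noise_sd = 0,
                    optical_bg_mean = 0, optical_bg_sd = 0, de_fraction = 0.25,
                    seed = 13)
  ds <- simulate_dataset(cfg)
  # summarization path isolated: quantile normalization maps both conditions
  # onto a common distribution and so perturbs genuine group differences;
  # background correction is meaningless without an additive background
  expr <- rma(ds$rna, ds$layout, background = FALSE, quantile = FALSE)
  dhat <- rowMeans(expr[, conditions(expr) == "ripe"]) -
    rowMeans(expr[, conditions(expr) == "unripe"])
  expect_equal(dhat, ds$truth$de_sets[rownames(expr)], tolerance = 1e-6)
})

test_that("rma is deterministic and equivariant to array order", {
  ds <- small_dataset()
  mask <- build_mask(ds$gdna, ds$layout, 75)
  masked <- apply_mask(ds$layout, mask)
  a <- rma(ds$rna, masked)
  b <- rma(ds$rna, masked)
  expect_identical(a, b)

  perm <- c(4, 1, 5, 2, 6, 3)
  p <- rma(ds$rna[perm], masked)
  expect_identical(colnames(p), colnames(a)[perm])
  expect_equal(unclass(p), unclass(a)[, perm], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("masking improves fold-change accuracy under heavy divergence", {
  cfg <- sim_config(n_probe_sets = 150, divergence_fraction = 0.5,
                    attenuation = 0.05, de_fraction = 0.2, seed = 14)
  ds <- simulate_dataset(cfg)
  de_sets <- names(ds$truth$de_sets)[ds$truth$de_sets != 0]
  err <- function(expr) {
    dhat <- rowMeans(expr[, conditions(expr) == "ripe"]) -
      rowMeans(expr[, conditions(expr) == "unripe"])
    keep <- intersect(de_sets, names(dhat))
    mean(abs(dhat[keep] - ds$truth$de_sets[keep]))
  }
  unmasked <- rma(ds$rna, ds$layout)
  mask <- build_mask(ds$gdna, ds$layout, 75)
  masked <- rma(ds$rna, apply_mask(ds$layout, mask))
  expect_lt(err(masked), err(unmasked))
})

test_that("rma rejects unusable inputs", {
  ds <- small_dataset()
  expect_error(rma(ds$rna[1], ds$layout), ">= 2 arrays")
  short <- ds$rna
  short[[1]]$intensities <- short[[1]]$intensities[-1]
  expect_error(rma(short, ds$layout), "missing retained probe")
})
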