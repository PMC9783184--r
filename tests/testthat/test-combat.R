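test_that("standardisation matches a hand computation on a small toy", {
  # 3 genes x 6 samples, two batches of 3; check gene 1 by direct arithmetic
  v <- rbind(c(1, 2, 3, 5, 6, 7),
             c(0, 0, 1, 1, 0, 0),
             c(2, 4, 6, 1, 3, 5))
  dimnames(v) <- list(paste0("g", 1:3), paste0("s", 1:6))
  fm <- feature_matrix(v, data.frame(sample_id = colnames(v), group = "g",
                                     batch = rep(c("A", "B"), each = 3)))
  model <- fit_combat(fm)

  # grand effect: batch means weighted by batch size (equal here)
  expect_equal(unname(model$alpha["g1"]), (2 + 6) / 2)
  # pooled variance: mean squared residual from per-batch means, divisor n
  res1 <- c(1, 2, 3) - 2
  res2 <- c(5, 6, 7) - 6
  expect_equal(unname(model$var_pooled["g1"]),
               sum(c(res1, res2)^2) / 6)
  # batch A mean of standardised gene 1
  z1 <- (c(1, 2, 3) - 4) / sqrt(model$var_pooled["g1"])
  expect_equal(unname(model$gamma_hat["g1", "A"]), mean(z1))
  expect_equal(unname(model$delta_hat["g1", "A"]), var(z1))
})

test_that("corrected output matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  sim <- simulate_expression(sim_config(seed = 7))
  fm <- sim$matrix
  mine <- apply_combat(fm, fit_combat(fm))$values
  ref <- suppressMessages(
    sva::ComBat(dat = fm$values, batch = fm$metadata$batch, mod = NULL,
                par.prior = TRUE, prior.plots = FALSE))
  expect_equal(mine, ref, tolerance = 1e-4)
})

test_that("duplicate batches produce near-null batch effects and identity correction", {
  set.seed(51)
  half <- matrix(rnorm(100 * 25, 8, 2), 100, 25)
  v <- cbind(half, half)
  dimnames(v) <- list(sprintf("g%03d", 1:100), sprintf("s%03d", 1:50))
  fm <- feature_matrix(v, data.frame(sample_id = colnames(v), group = "g",
                                     batch = rep(c("A", "B"), each = 25)))
  model <- fit_combat(fm)
  expect_lt(max(abs(model$gamma_star)), 1e-6)
  # standardised within-batch variance carries the n/(n-1) factor, not 1
  expect_equal(unname(model$delta_star[, "A"]), rep(25 / 24, 100),
               tolerance = 0.01)
  # identity up to the same n/(n-1) variance-ratio compression the
  # reference implementation applies
  corrected <- apply_combat(fm, model)
  expect_lt(max(abs(corrected$values - fm$values)), 0.2)
  expect_gt(cor(c(corrected$values), c(fm$values)), 0.9999)
})

test_that("planted shift and scale are recovered on the data scale", {
  fm <- two_batch_matrix(n_genes = 300, n_per_batch = c(50, 50),
                         shift = 2, scale = 1.5, seed = 52)
  model <- fit_combat(fm)
  est <- batch_effect_estimates(model, "B", reference = "A")
  expect_equal(mean(est$shift), 2, tolerance = 0.1)
  expect_equal(mean(est$scale), 1.5, tolerance = 0.15)
})

test_that("correction equalises per-gene batch means", {
  fm <- two_batch_matrix(n_genes = 200, n_per_batch = c(30, 30),
                         shift = 2, scale = 1.5, seed = 53)
  b <- fm$metadata$batch
  mean_gap <- function(v) {
    abs(rowMeans(v[, b == "A"]) - rowMeans(v[, b == "B"]))
  }
  before <- mean_gap(fm$values)
  after <- mean_gap(apply_combat(fm, fit_combat(fm))$values)
  expect_lt(mean(after), 0.05 * mean(before))
  expect_lt(max(after), 0.2 * max(before))
})

test_that("repeated correction is near-idempotent and pooled means are kept", {
  fm <- two_batch_matrix(n_genes = 200, n_per_batch = c(25, 25),
                         shift = 1.5, scale = 1.3, seed = 54)
  once <- apply_combat(fm, fit_combat(fm))
  twice <- apply_combat(once, fit_combat(once))
  first_change <- max(abs(once$values - fm$values))
  second_change <- max(abs(twice$values - once$values))
  expect_lt(second_change, 0.1 * first_change)
  # location-scale model preserves the per-gene pooled intercept
  expect_equal(rowMeans(once$values), rowMeans(fm$values), tolerance = 0.02)
})

test_that("shrinkage weakens as the batch grows", {
  pull <- function(n) {
    fm <- two_batch_matrix(n_genes = 150, n_per_batch = c(n, n),
                           shift = 1, scale = 1.2, seed = 55)
    model <- fit_combat(fm)
    mean(abs(model$gamma_star[, "B"] - model$gamma_hat[, "B"]))
  }
  expect_lt(pull(40), pull(5))
})

test_that("degenerate designs are rejected or flagged", {
  fm <- two_batch_matrix(n_genes = 20, n_per_batch = c(5, 5), seed = 56)
  expect_error(fit_combat(fm, batch = c(rep("A", 9), "B")), "single-sample")
  expect_error(fit_combat(fm, batch = rep("A", 10)), ">= 2 batches")

  # batch confounded 1:1 with group: warn, don't fail
  fm$metadata$group <- fm$metadata$batch
  expect_warning(fit_combat(fm), "confound|coincides")

  # unseen batch at apply time
  model <- suppressWarnings(fit_combat(fm))
  expect_error(apply_combat(fm, model, batch = c(rep("A", 5), rep("C", 5))),
               "not in model")

  # flat-within-every-batch genes pass through unchanged
  v <- fm$values
  v[3, ] <- rep(c(2, 7), each = 5)  # constant within each batch
  fm2 <- feature_matrix(v, data.frame(sample_id = colnames(v), group = "g",
                                      batch = rep(c("A", "B"), each = 5)))
  model2 <- fit_combat(fm2)
  expect_true("g003" %in% model2$passthrough)
  corr <- apply_combat(fm2, model2)
  expect_equal(corr$values["g003", ], v["g003", ])
})

test_that("symbol harmonisation merges case-variant gene labels", {
  sim <- simulate_expression(sim_config(seed = 57, uppercase_fraction = 0.3))
  expect_false(is.null(sim$parts))
  merged <- suppressMessages(merge_by_symbol(sim$parts$tissue,
                                             sim$parts$culture))
  expect_identical(dim(merged$values), dim(sim$matrix$values))
  # values identical to the unsplit matrix after sample reordering
  expect_equal(merged$values[, colnames(sim$matrix$values)],
               sim$matrix$values)

  # one-to-many collision resolves to the higher-mean row
  v1 <- rbind(Abc = c(1, 2), ABC = c(10, 20), Xyz = c(3, 4))
  colnames(v1) <- c("a1", "a2")
  v2 <- rbind(ABC = c(5, 6), XYZ = c(7, 8))
  colnames(v2) <- c("b1", "b2")
  f1 <- feature_matrix(v1, data.frame(sample_id = colnames(v1), group = "x"))
  f2 <- feature_matrix(v2, data.frame(sample_id = colnames(v2), group = "y"))
  m <- suppressMessages(merge_by_symbol(f1, f2))
  expect_identical(sort(rownames(m$values)), c("ABC", "Xyz"))
  expect_equal(unname(m$values["ABC", c("a1", "a2")]), c(10, 20))
})
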