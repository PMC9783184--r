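# Textbook pooled-variance two-sample t, written independently of the
# package's code path; the oracle for differential_test's p-values.
pooled_t_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

test_that("differential_test computes exact fold changes and flat-feature behaviour", {
  fm <- tiny_lipid_matrix(c(5, 5, 5, 5,
                            4, 4, 1, 1))
  expect_warning(res <- differential_test(fm, "A", "B", pseudocount = 0),
                 "zero-variance")
  expect_equal(res$log2_fold_change[1], 0)
  expect_false(res$significant[1])
  expect_identical(res$direction[1], "ns")
  # (4,4) vs (1,1): exact 4-fold ratio
  expect_equal(res$log2_fold_change[2], 2)
  expect_equal(res$p_value, c(1, 1))  # both zero-variance on the log scale
})

test_that("t p-values match an independent textbook computation", {
  lip <- simulate_lipidomics(sim_config(seed = 21, species_per_class = 5))
  res <- differential_test(lip$matrix, "WDLPS", "DDLPS", pseudocount = 0)
  v <- lip$matrix$values
  ga <- samples_in_group(lip$matrix, "WDLPS")
  gb <- samples_in_group(lip$matrix, "DDLPS")
  oracle <- apply(log2(v), 1, function(r) pooled_t_pvalue(r[ga], r[gb]))
  expect_equal(res$p_value, unname(oracle), tolerance = 1e-12)

  welch <- differential_test(lip$matrix, "WDLPS", "DDLPS", test = "welch",
                             pseudocount = 0)
  oracle_w <- apply(log2(v), 1, function(r) {
    x <- r[ga]; y <- r[gb]
    se2 <- var(x) / length(x) + var(y) / length(y)
    df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                     (var(y) / length(y))^2 / (length(y) - 1))
    2 * pt(-abs((mean(x) - mean(y)) / sqrt(se2)), df)
  })
  expect_equal(welch$p_value, unname(oracle_w), tolerance = 1e-12)
})

test_that("differential_test is antisymmetric under group swap", {
  lip <- simulate_lipidomics(sim_config(seed = 22, species_per_class = 4))
  for (tst in c("t", "wilcoxon", "ks")) {
    ab <- differential_test(lip$matrix, "WDLPS", "DDLPS", test = tst)
    ba <- differential_test(lip$matrix, "DDLPS", "WDLPS", test = tst)
    expect_equal(ab$log2_fold_change, -ba$log2_fold_change, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
})

test_that("groups with fewer than two samples are rejected", {
  fm <- tiny_lipid_matrix(c(1, 2, 3, 4), groups = c("A", "B", "B", "B"))
  expect_error(differential_test(fm, "A", "B"), ">= 2 samples")
})

test_that("volcano gate counts match direct filtering and behave monotonically", {
  res <- data.frame(
    feature_id = c("f1", "f2", "f3"),
    log2_fold_change = c(1.5, -1.5, 1.5),
    p_value = c(0.01, 0.01, 0.2),
    stringsAsFactors = FALSE)
  g <- volcano_gate(res, log2fc_threshold = 1, alpha = 0.05)
  expect_identical(c(g$n_up, g$n_down), c(1L, 1L))

  empty <- volcano_gate(res[0, ], 1, 0.05)
  expect_identical(c(empty$n_up, empty$n_down), c(0L, 0L))
  expect_identical(nrow(empty$gated), 0L)

  # monotone in alpha, antitone in the fold-change threshold
  lip <- simulate_lipidomics(sim_config(seed = 23))
  dr <- differential_test(lip$matrix, "WDLPS", "DDLPS")
  n_of <- function(th, al) {
    g <- volcano_gate(dr, th, al); g$n_up + g$n_down
  }
  expect_true(n_of(1, 0.01) <= n_of(1, 0.05))
  expect_true(n_of(2, 0.05) <= n_of(1, 0.05))
  expect_true(n_of(1, 0.05) <= nrow(dr))
})

test_that("top-k selection follows the documented p / |FC| / lexical tie-break", {
  res <- data.frame(
    feature_id = c("b", "a", "c", "d"),
    log2_fold_change = c(2, 1, -2, 3),
    p_value = c(0.01, 0.02, 0.01, 0.5),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  expect_identical(top_k_by_significance(res, 1), "b")  # tie on p: |FC| 2 beats c? both 2 -> lexical b < c
  expect_identical(top_k_by_significance(res, 3), c("b", "c", "a"))
  expect_warning(sel <- top_k_by_significance(res, 4), "only 3")
  expect_identical(sel, c("b", "c", "a"))

  # tie in p and |FC| resolved lexically
  res$log2_fold_change <- c(2, 2, 2, 3)
  res$p_value <- c(0.01, 0.01, 0.01, 0.5)
  expect_identical(top_k_by_significance(res, 2), c("a", "b"))
})

test_that("top-k on simulated data equals an independent sort-then-slice", {
  lip <- simulate_lipidomics(sim_config(seed = 24))
  dr <- differential_test(lip$matrix, "WDLPS", "DDLPS")
  k <- 48
  sel <- top_k_by_significance(dr, k)
  sig <- dr[dr$significant, ]
  oracle <- sig[order(sig$p_value, -abs(sig$log2_fold_change),
                      sig$feature_id), "feature_id"][seq_len(k)]
  expect_identical(sel, oracle)
})

test_that("PCA scores agree with a covariance eigendecomposition oracle", {
  set.seed(31)
  v <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:8)))
  fm <- feature_matrix(v, data.frame(sample_id = colnames(v), group = "g"))
  pc <- pca_scores(fm, n_components = 3)

  x <- scale(t(v), center = TRUE, scale = FALSE)
  eg <- eigen(cov(x), symmetric = TRUE)
  scores_oracle <- x %*% eg$vectors[, 1:3]
  for (j in 1:3) {  # eigenvectors defined up to sign
    expect_equal(abs(unname(pc$scores[, j])), abs(unname(scores_oracle[, j])),
                 tolerance = 1e-8)
  }
  ev_oracle <- eg$values / sum(eg$values)
  expect_equal(pc$explained_variance, ev_oracle[1:3], tolerance = 1e-8)
})

test_that("PCA satisfies its structural invariants", {
  lip <- simulate_lipidomics(sim_config(seed = 32))
  pc <- pca_scores(lip$matrix, n_components = 4)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)
  expect_equal(unname(colMeans(pc$scores)), rep(0, 4), tolerance = 1e-8)
  cv <- cov(pc$scores)
  offdiag <- cv; diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)) / max(diag(cv)), 1e-6)

  # duplicate samples share coordinates
  v <- lip$matrix$values[, c(1, 1, 2, 3)]
  colnames(v) <- paste0("t", 1:4)
  fm <- feature_matrix(v, data.frame(sample_id = colnames(v), group = "g"))
  sc <- pca_scores(fm, 2)$scores
  expect_equal(sc[1, ], sc[2, ], tolerance = 1e-8)

  # rank-1 structure concentrates variance on PC1
  r1 <- outer(rnorm(30), rnorm(6)) + 5
  dimnames(r1) <- list(paste0("f", 1:30), paste0("s", 1:6))
  fm1 <- feature_matrix(r1, data.frame(sample_id = colnames(r1), group = "g"))
  expect_gte(pca_scores(fm1, 1)$explained_variance[1], 0.999)

  cm <- matrix(3, 5, 4, dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
  fmc <- feature_matrix(cm, data.frame(sample_id = colnames(cm), group = "g"))
  expect_error(pca_scores(fmc, 1), "constant")
})

test_that("set_overlap produces a valid Venn partition", {
  ov <- set_overlap(list(A = c("a", "b"), B = c("b", "c")))
  expect_identical(ov$size[ov$pattern == "A&B"], 1L)
  expect_identical(ov$size[ov$pattern == "A"], 1L)
  expect_identical(ov$size[ov$pattern == "B"], 1L)
  expect_identical(sum(ov$size), 3L)  # size of the union

  same <- set_overlap(list(x = letters[1:4], y = letters[1:4]))
  expect_identical(same$pattern, "x&y")
  expect_identical(same$size, 4L)

  # random sets vs an exhaustive membership scan
  set.seed(33)
  sets <- list(u = sample(letters, 12), v = sample(letters, 9),
               w = sample(letters, 15))
  ov3 <- set_overlap(sets)
  uni <- unique(unlist(sets))
  expect_identical(sum(ov3$size), length(uni))
  for (i in seq_len(nrow(ov3))) {
    in_sets <- names(sets)[unlist(ov3[i, names(sets)])]
    n_direct <- sum(vapply(uni, function(el) {
      setequal(names(sets)[vapply(sets, function(s) el %in% s, TRUE)], in_sets)
    }, TRUE))
    expect_identical(ov3$size[i], n_direct)
  }
})
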