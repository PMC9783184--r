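#' Per-feature two-group differential testing
#'
#' For every feature (lipid species, lipid class, or gene) computes a log2
#' fold change of group A over group B and a two-sided p-value from the
#' chosen test. Fold changes are computed on group means of the raw values
#' after adding a pseudocount, `log2(mean_A + pc) - log2(mean_B + pc)`;
#' the t-tests run on `log2(value + pc)` per sample, while the Wilcoxon
#' rank-sum and Kolmogorov-Smirnov tests are rank/ECDF based and use the
#' raw values.
#'
#' @param fm a [feature_matrix()].
#' @param group_a,group_b group labels to compare (A over B); each must
#'   have at least two samples.
#' @param test `"t"` (two-sample Student's t with pooled variance,
#'   default), `"welch"` (unequal-variance t), `"wilcoxon"`, or `"ks"`.
#' @param pseudocount added before log transforms; default is half the
#'   smallest nonzero value in the matrix (0 if the matrix has no zeros).
#' @param log2fc_threshold,alpha gate used for the `significant`/`direction`
#'   call; a feature is significant when `|log2FC| > log2fc_threshold` and
#'   `p < alpha`. Defaults encode a 2-fold change at p < 0.05.
#' @param adjust `"none"` (default, raw p-values as in volcano-style gates)
#'   or `"BH"` for Benjamini-Hochberg adjusted p-values.
#' @param values_are_log set `TRUE` when the matrix is already on the log2
#'   scale (e.g. log-transformed or batch-corrected expression): the log2
#'   fold change is then the difference of group means, no pseudocount or
#'   further log transform is applied, and all tests run on the values as
#'   given.
#' @return data.frame with columns `feature_id`, `log2_fold_change`,
#'   `p_value`, `test_used`, `significant`, `direction` (`"up"`, `"down"`,
#'   `"ns"`).
#' @examples
#' sim <- simulate_lipidomics(sim_config(seed = 1))
#' res <- differential_test(sim$matrix, "WDLPS", "DDLPS")
#' table(res$direction)
#' @export
differential_test <- function(fm, group_a, group_b,
                              test = c("t", "welch", "wilcoxon", "ks"),
                              pseudocount = NULL,
                              log2fc_threshold = 1, alpha = 0.05,
                              adjust = c("none", "BH"),
                              values_are_log = FALSE) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  sa <- samples_in_group(fm, group_a)
  sb <- samples_in_group(fm, group_b)
  if (length(sa) < 2L || length(sb) < 2L) {
    stop("both groups need >= 2 samples (", group_a, ": ", length(sa),
         ", ", group_b, ": ", length(sb), ")")
  }
  if (is.null(pseudocount)) pseudocount <- default_pseudocount(fm$values)
  if (pseudocount < 0) stop("pseudocount must be >= 0")

  A <- fm$values[, sa, drop = FALSE]
  B <- fm$values[, sb, drop = FALSE]
  if (values_are_log) {
    l2fc <- rowMeans(A) - rowMeans(B)
    lA <- A
    lB <- B
  } else {
    l2fc <- log2(rowMeans(A) + pseudocount) - log2(rowMeans(B) + pseudocount)
    lA <- log2(A + pseudocount)
    lB <- log2(B + pseudocount)
  }
  n_const <- 0L
  p <- vapply(seq_len(nrow(A)), function(i) {
    switch(test,
      t = ,
      welch = {
        if (stats::var(lA[i, ]) == 0 && stats::var(lB[i, ]) == 0) {
          n_const <<- n_const + 1L
          1
        } else {
          stats::t.test(lA[i, ], lB[i, ], var.equal = test == "t")$p.value
        }
      },
      wilcoxon = suppressWarnings(
        stats::wilcox.test(A[i, ], B[i, ], exact = FALSE)$p.value),
      ks = suppressWarnings(
        stats::ks.test(A[i, ], B[i, ])$p.value))
  }, 0.0)
  if (n_const > 0L) {
    warning(n_const, " zero-variance feature(s) under the t-test; p set to 1")
  }
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")

  sig <- abs(l2fc) > log2fc_threshold & p < alpha
  direction <- ifelse(!sig, "ns", ifelse(l2fc > 0, "up", "down"))
  data.frame(feature_id = rownames(fm$values),
             log2_fold_change = unname(l2fc),
             p_value = p, test_used = test,
             significant = sig, direction = direction,
             stringsAsFactors = FALSE)
}

default_pseudocount <- function(values) {
  nz <- values[values > 0]
  if (any(values == 0) && length(nz)) min(nz) / 2 else 0
}

#' Volcano gate: count and extract up/down-regulated features
#'
#' Applies the standard volcano-plot gate, `|log2FC| > threshold` and
#' `p < alpha`, to a differential-test result and reports the number of
#' up- and down-regulated features plus the gated subset. With the default
#' threshold of 1 the gate corresponds to a 2-fold change; the same gate is
#' used for lipid species and for genes.
#'
#' @param results data.frame from [differential_test()].
#' @param log2fc_threshold positive log2 fold-change threshold.
#' @param alpha positive significance level.
#' @return list with `n_up`, `n_down`, and `gated` (rows of `results`
#'   passing the gate, with recomputed `significant`/`direction`).
#' @export
volcano_gate <- function(results, log2fc_threshold = 1, alpha = 0.05) {
  stopifnot(log2fc_threshold > 0, alpha > 0)
  if (nrow(results) == 0L) {
    return(list(n_up = 0L, n_down = 0L, gated = results))
  }
  pass <- abs(results$log2_fold_change) > log2fc_threshold &
    results$p_value < alpha
  gated <- results[pass, , drop = FALSE]
  gated$significant <- TRUE
  gated$direction <- ifelse(gated$log2_fold_change > 0, "up", "down")
  list(n_up = sum(gated$direction == "up"),
       n_down = sum(gated$direction == "down"),
       gated = gated)
}

#' Select the top-k most significant features (heatmap shortlist)
#'
#' Ranks significant features by ascending p-value, breaking ties by larger
#' absolute log2 fold change and then lexically by feature id, and returns
#' the first `k`. This is the deterministic "top altered features" selection
#' used to pick heatmap rows.
#'
#' @param results data.frame from [differential_test()].
#' @param k number of features to select; if fewer than `k` features are
#'   significant, all significant features are returned with a warning.
#' @return character vector of selected feature ids, in rank order.
#' @export
top_k_by_significance <- function(results, k) {
  stopifnot(k >= 1, k <= nrow(results))
  sig <- results[results$significant, , drop = FALSE]
  ord <- order(sig$p_value, -abs(sig$log2_fold_change), sig$feature_id)
  sig <- sig[ord, , drop = FALSE]
  if (nrow(sig) < k) {
    warning("only ", nrow(sig), " significant features for k = ", k)
    return(sig$feature_id)
  }
  sig$feature_id[seq_len(k)]
}

#' PCA sample scores for a feature matrix
#'
#' Principal component analysis over samples: features are centred (and
#' optionally unit-variance scaled), and samples are projected onto the
#' leading components. Centering-only is the default for abundance data;
#' autoscaling is available for matrices mixing very different feature
#' scales.
#'
#' @param fm a [feature_matrix()].
#' @param n_components number of components to keep; at most
#'   `min(features, samples - 1)`.
#' @param scaling `"center"` (default) or `"autoscale"` (unit variance;
#'   constant features are dropped first).
#' @return list with `scores` (samples x components, columns `PC1..`),
#'   `explained_variance` (fractions, non-increasing), and `metadata`
#'   (the sample sheet, for plotting).
#' @export
pca_scores <- function(fm, n_components = 2L,
                       scaling = c("center", "autoscale")) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  scaling <- match.arg(scaling)
  x <- t(fm$values)  # samples x features
  if (all(apply(x, 2L, stats::var) == 0)) {
    stop("constant matrix: no variance to decompose")
  }
  if (scaling == "autoscale") {
    keep <- apply(x, 2L, stats::var) > 0
    x <- x[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scaling == "autoscale")
  n_components <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       metadata = fm$metadata)
}

#' Venn partition sizes of two or more differential feature sets
#'
#' @param diff_sets named list of >= 2 character vectors of feature ids
#'   (each deduplicated).
#' @return data.frame with one row per non-empty membership pattern:
#'   `pattern` (e.g. `"A&B"`), one logical column per set, and `size`.
#'   Partition sizes sum to the size of the union.
#' @examples
#' set_overlap(list(A = c("a", "b"), B = c("b", "c")))
#' @export
set_overlap <- function(diff_sets) {
  stopifnot(is.list(diff_sets), length(diff_sets) >= 2L)
  if (is.null(names(diff_sets)) || any(!nzchar(names(diff_sets)))) {
    names(diff_sets) <- paste0("set", seq_along(diff_sets))
  }
  diff_sets <- lapply(diff_sets, unique)
  universe <- unique(unlist(diff_sets, use.names = FALSE))
  member <- vapply(diff_sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(diff_sets)))
  pat <- apply(member, 1L, function(r) {
    paste(names(diff_sets)[r], collapse = "&")
  })
  sizes <- table(pat)
  out <- data.frame(pattern = names(sizes), stringsAsFactors = FALSE)
  for (nm in names(diff_sets)) {
    out[[nm]] <- vapply(strsplit(out$pattern, "&", fixed = TRUE),
                        function(p) nm %in% p, TRUE)
  }
  out$size <- as.integer(sizes)
  out[order(-rowSums(out[names(diff_sets)]), out$pattern), , drop = FALSE]
}
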