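#' Fit a parametric empirical-Bayes batch-effect model
#'
#' Implements the parametric location-scale batch adjustment of Johnson,
#' Li & Rabinovic (2007): per-gene values are standardised against a
#' pooled grand mean and variance, per-batch additive (`gamma_hat`) and
#' multiplicative (`delta_hat`) effects are estimated on the standardised
#' scale, and both are shrunk towards batch-level priors (normal prior on
#' `gamma`, inverse-gamma prior on `delta`, hyperparameters by method of
#' moments) by iterating the conditional posterior means to convergence.
#'
#' Expression inputs are assumed to be on a log scale (see
#' [log2_transform()]); correction is additive on that scale. Genes with
#' zero variance inside every batch carry no estimable scale effect and are
#' flagged for pass-through. By default no biological covariates are
#' protected; supply `group` to keep group-mean differences out of the
#' batch estimates.
#'
#' @param fm a [feature_matrix()] whose metadata has a `batch` column (or
#'   pass `batch` explicitly).
#' @param batch optional character/factor of batch labels per sample,
#'   overriding `fm$metadata$batch`. At least 2 batches, each with >= 2
#'   samples.
#' @param group optional biological group labels to protect as model
#'   covariates while estimating batch effects.
#' @param tol convergence tolerance on successive `gamma_star`/`delta_star`
#'   iterates.
#' @param max_iter iteration cap for the conditional posterior-mean updates.
#' @return A `BatchModel` object: list with `batches`, `n_per_batch`,
#'   `alpha` (per-gene grand effects), `design_beta`, `var_pooled`,
#'   `gamma_hat`, `delta_hat`, `gamma_star`, `delta_star` (genes x batches),
#'   `hyper` (per-batch prior parameters), `passthrough` (genes skipped),
#'   and bookkeeping needed by [apply_combat()].
#' @references Johnson WE, Li C, Rabinovic A (2007). Adjusting batch
#'   effects in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1))  # already log2 scale
#' model <- fit_combat(sim$matrix)
#' corrected <- apply_combat(sim$matrix, model)
#' @export
fit_combat <- function(fm, batch = NULL, group = NULL,
                       tol = 1e-4, max_iter = 100L) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (is.null(batch)) batch <- fm$metadata$batch
  if (is.null(batch)) stop("no batch labels: supply 'batch' or metadata$batch")
  batch <- factor(batch)
  if (nlevels(batch) < 2L) stop("need >= 2 batches")
  n_per_batch <- table(batch)
  if (any(n_per_batch < 2L)) {
    stop("single-sample batch(es): ",
         paste(names(n_per_batch)[n_per_batch < 2L], collapse = ", "))
  }
  if (!is.null(group)) {
    conf <- table(batch, factor(group))
    if (all(rowSums(conf > 0) == 1L)) {
      warning("batch is confounded 1:1 with group; correction may remove ",
              "biological signal")
    }
  } else if (!is.null(fm$metadata$group)) {
    conf <- table(batch, factor(fm$metadata$group))
    if (all(rowSums(conf > 0) == 1L) && nlevels(factor(fm$metadata$group)) > 1L) {
      warning("batch coincides 1:1 with the sample groups; correction may ",
              "remove biological signal (pass 'group' to protect it)")
    }
  }

  Y <- fm$values
  n_array <- ncol(Y)
  B <- stats::model.matrix(~ 0 + batch)          # batch design
  colnames(B) <- levels(batch)
  X <- B
  if (!is.null(group)) {
    G <- stats::model.matrix(~ factor(group))[, -1, drop = FALSE]
    X <- cbind(B, G)
  }

  # per-gene within-batch variance; genes flat in every batch pass through
  wvar <- vapply(levels(batch), function(b) {
    sub <- Y[, batch == b, drop = FALSE]
    apply(sub, 1L, stats::var)
  }, numeric(nrow(Y)))
  passthrough <- rowSums(wvar > 0) == 0
  Yf <- Y[!passthrough, , drop = FALSE]
  if (nrow(Yf) == 0L) stop("all genes have zero within-batch variance")

  # least-squares gene-wise fit; grand effects weight batches by size
  beta_hat <- t(solve(crossprod(X), crossprod(X, t(Yf))))
  w <- as.numeric(n_per_batch) / n_array
  alpha <- as.numeric(beta_hat[, seq_len(nlevels(batch)), drop = FALSE] %*% w)
  stand_mean <- alpha %o% rep(1, n_array)
  if (!is.null(group)) {
    extra <- beta_hat[, -seq_len(nlevels(batch)), drop = FALSE] %*%
      t(X[, -seq_len(nlevels(batch)), drop = FALSE])
    stand_mean <- stand_mean + extra
  }
  var_pooled <- rowSums((Yf - t(X %*% t(beta_hat)))^2) / n_array
  if (any(var_pooled <= 0)) {
    # exact-fit genes: no residual scale to standardise against
    passthrough[!passthrough][var_pooled <= 0] <- TRUE
    keep <- var_pooled > 0
    Yf <- Yf[keep, , drop = FALSE]
    stand_mean <- stand_mean[keep, , drop = FALSE]
    var_pooled <- var_pooled[keep]
    beta_hat <- beta_hat[keep, , drop = FALSE]
    alpha <- alpha[keep]
  }
  Z <- (Yf - stand_mean) / sqrt(var_pooled)

  nb <- nlevels(batch)
  ng <- nrow(Z)
  gamma_hat <- matrix(NA_real_, ng, nb, dimnames = list(rownames(Z), levels(batch)))
  delta_hat <- gamma_hat
  for (j in seq_len(nb)) {
    sub <- Z[, batch == levels(batch)[j], drop = FALSE]
    gamma_hat[, j] <- rowMeans(sub)
    delta_hat[, j] <- apply(sub, 1L, stats::var)
  }
  delta_hat[delta_hat <= 0] <- .Machine$double.eps

  hyper <- lapply(seq_len(nb), function(j) {
    m <- mean(delta_hat[, j]); s2 <- stats::var(delta_hat[, j])
    list(gamma_bar = mean(gamma_hat[, j]),
         tau2 = stats::var(gamma_hat[, j]),
         a_prior = (2 * s2 + m^2) / s2,
         b_prior = (m * s2 + m^3) / s2)
  })
  names(hyper) <- levels(batch)

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (j in seq_len(nb)) {
    idx <- batch == levels(batch)[j]
    n_j <- sum(idx)
    Zj <- Z[, idx, drop = FALSE]
    h <- hyper[[j]]
    g_old <- gamma_hat[, j]
    d_old <- delta_hat[, j]
    for (it in seq_len(max_iter)) {
      g_new <- (n_j * h$tau2 * gamma_hat[, j] + d_old * h$gamma_bar) /
        (n_j * h$tau2 + d_old)
      sse <- rowSums((Zj - g_new)^2)
      d_new <- (h$b_prior + 0.5 * sse) / (n_j / 2 + h$a_prior - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    gamma_star[, j] <- g_old
    delta_star[, j] <- d_old
  }

  colnames(stand_mean) <- colnames(Yf)
  structure(list(
    batches = levels(batch), n_per_batch = as.integer(n_per_batch),
    sample_ids = colnames(Yf),
    genes = rownames(Z), passthrough = names(passthrough)[passthrough],
    alpha = stats::setNames(alpha, rownames(Z)),
    var_pooled = stats::setNames(var_pooled, rownames(Z)),
    stand_mean = stand_mean,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    hyper = hyper, protected_group = !is.null(group)
  ), class = "BatchModel")
}

#' @export
print.BatchModel <- function(x, ...) {
  cat(sprintf("<BatchModel> %d genes, %d batches (%s), %d pass-through\n",
              length(x$genes), length(x$batches),
              paste(x$batches, collapse = ", "), length(x$passthrough)))
  invisible(x)
}

#' Apply a fitted batch model to a matrix
#'
#' Standardises each gene, removes the shrunken additive batch effect,
#' rescales by the shrunken batch scale, and back-transforms to the
#' original location/scale. Pass-through genes (flat within every batch)
#' are returned unchanged.
#'
#' @param fm the [feature_matrix()] to correct (same samples the model was
#'   fitted on, or a subset; batch labels must all be known to the model).
#' @param model a `BatchModel` from [fit_combat()].
#' @param batch optional batch labels overriding `fm$metadata$batch`.
#' @return A corrected `FeatureMatrix` with identical dimensions.
#' @export
apply_combat <- function(fm, model, batch = NULL) {
  stopifnot(inherits(fm, "FeatureMatrix"), inherits(model, "BatchModel"))
  if (is.null(batch)) batch <- fm$metadata$batch
  if (is.null(batch)) stop("no batch labels")
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen)) {
    stop("batch label(s) not in model: ", paste(unseen, collapse = ", "))
  }
  out <- fm$values
  genes <- intersect(rownames(out), model$genes)
  if (length(genes) == 0L) stop("no modelled genes present in matrix")
  gi <- match(genes, model$genes)
  Y <- out[genes, , drop = FALSE]
  sm <- if (model$protected_group) {
    # covariate effects were kept out of the batch estimates; restore the
    # full fitted mean, which is only defined for the fitting samples
    if (!all(colnames(Y) %in% model$sample_ids)) {
      stop("group-protected model can only correct the samples it was fitted on")
    }
    model$stand_mean[gi, match(colnames(Y), model$sample_ids), drop = FALSE]
  } else {
    model$alpha[gi] %o% rep(1, ncol(Y))
  }
  Z <- (Y - sm) / sqrt(model$var_pooled[gi])
  for (b in unique(batch)) {
    j <- match(b, model$batches)
    idx <- batch == b
    Z[, idx] <- (Z[, idx, drop = FALSE] - model$gamma_star[gi, j]) /
      sqrt(model$delta_star[gi, j])
  }
  out[genes, ] <- Z * sqrt(model$var_pooled[gi]) + sm
  feature_matrix(out, fm$metadata)
}

#' Raw-scale batch-effect estimates from a fitted model
#'
#' Back-transforms the shrunken standardised-scale estimates to the data
#' scale: per-gene additive shift of each batch relative to a reference
#' batch (`gamma_star` difference times the pooled standard deviation) and
#' the multiplicative noise-scale ratio (`sqrt` of the `delta_star` ratio).
#' Useful for checking recovered effects against known/planted ones.
#'
#' @param model a `BatchModel`.
#' @param batch batch whose effect is reported.
#' @param reference reference batch (default: the model's first batch).
#' @return data.frame with `gene`, `shift` (additive, data scale), and
#'   `scale` (multiplicative, standard-deviation ratio).
#' @export
batch_effect_estimates <- function(model, batch, reference = model$batches[1]) {
  stopifnot(inherits(model, "BatchModel"),
            batch %in% model$batches, reference %in% model$batches)
  j <- match(batch, model$batches)
  r <- match(reference, model$batches)
  data.frame(
    gene = model$genes,
    shift = (model$gamma_star[, j] - model$gamma_star[, r]) *
      sqrt(model$var_pooled),
    scale = sqrt(model$delta_star[, j] / model$delta_star[, r]),
    stringsAsFactors = FALSE)
}

#' Merge two expression matrices by case-insensitive gene symbol
#'
#' Tumor/normal tissue data and a cell-culture differentiation course may
#' come from different species whose gene symbols differ only in case
#' (e.g. human upper-case vs mouse title-case). Genes are matched by
#' upper-cased symbol; genes present in only one matrix are dropped with a
#' message reporting the count, and when several rows of one matrix
#' collapse to the same symbol the row with the higher mean is kept. The
#' merged matrix uses the first matrix's spelling of each symbol.
#'
#' @param fm_x,fm_y two [feature_matrix()] objects with disjoint sample
#'   ids.
#' @return A merged `FeatureMatrix` over the shared gene set, with the
#'   row-bound metadata of both inputs.
#' @export
merge_by_symbol <- function(fm_x, fm_y) {
  stopifnot(inherits(fm_x, "FeatureMatrix"), inherits(fm_y, "FeatureMatrix"))
  if (length(intersect(colnames(fm_x$values), colnames(fm_y$values)))) {
    stop("sample ids overlap between the two matrices")
  }
  dedupe <- function(v) {
    key <- toupper(rownames(v))
    if (!anyDuplicated(key)) return(v)
    keep <- tapply(seq_len(nrow(v)), key, function(idx) {
      idx[which.max(rowMeans(v[idx, , drop = FALSE]))]
    })
    v[sort(as.integer(keep)), , drop = FALSE]
  }
  vx <- dedupe(fm_x$values)
  vy <- dedupe(fm_y$values)
  shared <- intersect(toupper(rownames(vx)), toupper(rownames(vy)))
  n_drop <- (nrow(vx) - length(shared)) + (nrow(vy) - length(shared))
  if (length(shared) == 0L) stop("no shared gene symbols")
  if (n_drop > 0L) {
    message(n_drop, " gene(s) without a cross-matrix match dropped; ",
            length(shared), " shared")
  }
  ix <- match(shared, toupper(rownames(vx)))
  iy <- match(shared, toupper(rownames(vy)))
  merged <- cbind(vx[ix, , drop = FALSE], vy[iy, , drop = FALSE])
  rownames(merged) <- rownames(vx)[ix]
  meta_cols <- union(names(fm_x$metadata), names(fm_y$metadata))
  pad <- function(df) {
    for (nm in setdiff(meta_cols, names(df))) df[[nm]] <- NA
    df[meta_cols]
  }
  feature_matrix(merged, rbind(pad(fm_x$metadata), pad(fm_y$metadata)))
}

#' log2(x + 1) transform of a FeatureMatrix
#'
#' Conventional variance-stabilising transform for count-derived expression
#' applied upstream of batch correction and staging.
#'
#' @param fm a [feature_matrix()].
#' @param offset added before the log (default 1).
#' @return The transformed `FeatureMatrix`.
#' @export
log2_transform <- function(fm, offset = 1) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  feature_matrix(log2(fm$values + offset), fm$metadata)
}
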