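#' Stage a tumor group against an adipogenic differentiation time course
#'
#' For each differentiation day `d`, the mean corrected expression profile
#' of the SVF replicates at that day, `x_d`, is compared with the tumor
#' group mean `T` and the normal-tissue mean `N` by Euclidean distance:
#' `d_T = ||x_d - T||`, `d_N = ||x_d - N||`. The normal-referenced relative
#' distance is `d_T - d_N` and the similarity score is its reciprocal,
#' `1 / (d_T - d_N)`. A day whose SVF profile sits closer to the tumor than
#' to normal tissue has a negative relative distance; the best-matching
#' differentiation stage (`best_day`) is the day minimising the relative
#' distance, which is well-defined whatever the sign of the score. A
#' display-oriented magnitude score `1 / |d_T - d_N|` ("higher bar = more
#' similar") is also reported, flagged as non-literal.
#'
#' The matrix should already be batch-corrected ([apply_combat()]) and on a
#' log scale; distances use the full shared gene set with no weighting.
#'
#' @param fm corrected [feature_matrix()] containing the tumor, normal, and
#'   time-course samples; time-course samples must carry a `day` in the
#'   metadata.
#' @param tumor_group,normal_group,svf_group group labels of the tumor
#'   samples, the normal-tissue reference, and the differentiation
#'   time-course samples.
#' @param days days to profile; default: all days observed for
#'   `svf_group`, ascending. Missing requested days are dropped with a
#'   warning.
#' @param tolerance |d_T - d_N| below this is treated as a degenerate
#'   denominator and the reciprocal similarity is flagged undefined.
#' @return A `StageSimilarityProfile`: list with `tumor_group`, `days`, and
#'   a `profile` data.frame (one row per day: `day`, `d_T`, `d_N`,
#'   `relative_distance`, `similarity`, `similarity_magnitude`,
#'   `undefined`, `is_best`, `tied`), plus `best_day`.
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1))
#' corrected <- apply_combat(sim$matrix, fit_combat(sim$matrix))
#' stage_similarity(corrected, "WDLPS", "normal", "SVF")$best_day
#' @export
stage_similarity <- function(fm, tumor_group, normal_group, svf_group,
                             days = NULL, tolerance = 1e-9) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  meta <- fm$metadata
  st <- samples_in_group(fm, tumor_group)
  sn <- samples_in_group(fm, normal_group)
  sv <- samples_in_group(fm, svf_group)
  if (!length(st)) stop("no samples in tumor group '", tumor_group, "'")
  if (!length(sn)) stop("no samples in normal group '", normal_group, "'")
  if (!length(sv)) stop("no samples in time-course group '", svf_group, "'")
  svf_days <- meta$day[match(sv, meta$sample_id)]
  if (anyNA(svf_days)) stop("every '", svf_group, "' sample needs a day")
  observed <- sort(unique(svf_days))
  if (is.null(days)) {
    days <- observed
  } else {
    missing_days <- setdiff(days, observed)
    if (length(missing_days)) {
      warning("day(s) with no SVF samples omitted: ",
              paste(missing_days, collapse = ", "))
      days <- sort(intersect(days, observed))
    }
  }
  if (!length(days)) stop("no usable days")
  days <- as.integer(days)

  T_bar <- rowMeans(fm$values[, st, drop = FALSE])
  N_bar <- rowMeans(fm$values[, sn, drop = FALSE])

  prof <- do.call(rbind, lapply(days, function(d) {
    x_d <- rowMeans(fm$values[, sv[svf_days == d], drop = FALSE])
    d_T <- sqrt(sum((x_d - T_bar)^2))
    d_N <- sqrt(sum((x_d - N_bar)^2))
    rel <- d_T - d_N
    undef <- abs(rel) < tolerance
    data.frame(day = d, d_T = d_T, d_N = d_N, relative_distance = rel,
               similarity = if (undef) NA_real_ else 1 / rel,
               similarity_magnitude = if (undef) NA_real_ else 1 / abs(rel),
               undefined = undef)
  }))

  best_idx <- which(prof$relative_distance <=
                      min(prof$relative_distance) + tolerance)
  prof$is_best <- seq_len(nrow(prof)) == best_idx[1]  # earliest day on ties
  prof$tied <- length(best_idx) > 1 & seq_len(nrow(prof)) %in% best_idx
  structure(list(tumor_group = tumor_group, normal_group = normal_group,
                 svf_group = svf_group, days = days, profile = prof,
                 best_day = prof$day[prof$is_best]),
            class = "StageSimilarityProfile")
}

#' @export
print.StageSimilarityProfile <- function(x, ...) {
  cat(sprintf("<StageSimilarityProfile> %s vs %s over days %s\n",
              x$tumor_group, x$normal_group, paste(x$days, collapse = ",")))
  cat(sprintf("best-matching day: %d%s\n", x$best_day,
              if (any(x$profile$tied)) " (tied)" else ""))
  print(x$profile, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-day similarity table for bar-plot export
#'
#' Flattens a [stage_similarity()] profile into one row per day, ordered by
#' day, with the undefined flag kept as a column (an undefined day carries
#' `NA` similarity, never a number).
#'
#' @param profile a `StageSimilarityProfile`.
#' @return data.frame with columns `tumor_group`, `day`, `d_T`, `d_N`,
#'   `relative_distance`, `similarity`, `similarity_magnitude`,
#'   `undefined`, `best_day`.
#' @export
similarity_barplot_table <- function(profile) {
  stopifnot(inherits(profile, "StageSimilarityProfile"))
  out <- profile$profile[order(profile$profile$day), , drop = FALSE]
  data.frame(tumor_group = profile$tumor_group, out[
    , c("day", "d_T", "d_N", "relative_distance", "similarity",
        "similarity_magnitude", "undefined")],
    best_day = out$is_best, row.names = NULL, stringsAsFactors = FALSE)
}

#' Stability of the stage call under gene subsampling
#'
#' Diagnostic: recomputes [stage_similarity()] on random subsets of the
#' genes and reports how often the best-matching day agrees with the
#' full-set call. Well-separated data should be stable (agreement near 1).
#'
#' @param fm corrected [feature_matrix()].
#' @param tumor_group,normal_group,svf_group as in [stage_similarity()].
#' @param fraction fraction of genes per resample (default 0.8).
#' @param n_resamples number of resamples.
#' @param seed RNG seed for the subsampling.
#' @return list with `best_day` (full-set call), `agreement` (fraction of
#'   resamples matching it), and `calls` (per-resample best days).
#' @export
stage_stability <- function(fm, tumor_group, normal_group, svf_group,
                            fraction = 0.8, n_resamples = 50L, seed = 1L) {
  full <- stage_similarity(fm, tumor_group, normal_group, svf_group)
  ng <- nrow(fm$values)
  k <- max(2L, round(fraction * ng))
  rng <- local({ set.seed(seed); lapply(seq_len(n_resamples), function(i)
    sample.int(ng, k)) })
  calls <- vapply(rng, function(idx) {
    stage_similarity(fm[idx, ], tumor_group, normal_group, svf_group)$best_day
  }, 0)
  list(best_day = full$best_day,
       agreement = mean(calls == full$best_day),
       calls = calls)
}
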