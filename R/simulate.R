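#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators with defaults
#' emulating the study design the package targets: two tumor groups (6 and
#' 7 patients) whose transcriptomes resemble distinct adipogenic
#' differentiation stages, paired normal tissue (13 samples, mature
#' profile), an SVF differentiation time course over days 0-10 with 3
#' replicates per day, a tissue-vs-cell-culture batch split with additive
#' and multiplicative effects, and a lipidome in which neutral storage
#' lipids (TG/DG) are up in the well-differentiated group while membrane
#' phospholipids and sphingomyelin (PC/PE/SM, plus ChE) are up in the
#' dedifferentiated group.
#'
#' @param seed integer RNG seed; identical configs and seeds give
#'   bit-identical outputs.
#' @param n_genes total genes in the expression matrices.
#' @param n_program_genes genes carrying the differentiation-program
#'   trajectory.
#' @param days differentiation days sampled in the time course (ascending).
#' @param svf_replicates replicates per day in the time course.
#' @param stage_assignment named integer vector: tumor group -> the
#'   differentiation day its expression resembles. Must be days in `days`.
#' @param n_tumor named integer vector of samples per tumor group (names
#'   must match `stage_assignment`).
#' @param n_normal normal-tissue samples.
#' @param sigmoid_midpoint,midpoint_spread,sigmoid_slope shape of the
#'   monotone per-gene sigmoid trajectories: each program gene switches at
#'   its own midpoint, drawn uniformly from
#'   `sigmoid_midpoint +/- midpoint_spread` (days), with a common slope.
#'   The defaults spread activation midpoints across the whole course,
#'   emulating the phased activation of early, intermediate, and late
#'   adipogenesis genes.
#' @param program_amplitude upper bound of per-gene trajectory amplitude
#'   (log2 units; amplitudes drawn uniformly in `[1, program_amplitude]`
#'   with random sign).
#' @param malignancy_n,malignancy_effect size and per-gene log2 effect of
#'   the tumor-specific signature shared by both tumor groups.
#' @param normal_signature_n,normal_signature_effect size and per-gene
#'   log2 effect of the tissue-context signature carried by normal tissue
#'   only: bulk normal fat contains vasculature, immune cells, and matrix
#'   programs that neither the tumors nor the cultured time course express.
#' @param noise_sd residual Gaussian noise (log2 units).
#' @param batch_shift,batch_scale additive shift (log2 units) and noise
#'   standard-deviation multiplier applied to the cell-culture batch.
#' @param lipid_classes lipid classes simulated (must be in the parser
#'   registry).
#' @param species_per_class species per lipid class.
#' @param class_log2_effects named numeric: per-class log2 group effect of
#'   group A over group B (unlisted classes get 0). The default plants
#'   TG/DG up in group A and PC/PE/SM/ChE up in group B.
#' @param lipid_groups named integer vector of lipidomics samples per
#'   group (first name is group A, second group B).
#' @param lipid_dispersion within-class species-level log2 standard
#'   deviation.
#' @param count_mode if `TRUE`, expression is emitted as Poisson-lognormal
#'   counts (requiring [log2_transform()] downstream) instead of directly
#'   on the log2 scale.
#' @param uppercase_fraction fraction of time-course gene labels
#'   upper-cased to emulate cross-species symbol style differences.
#' @return A `SimulationConfig` (validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_program_genes = 400L,
                       days = c(0L, 2L, 4L, 6L, 8L, 10L),
                       svf_replicates = 3L,
                       stage_assignment = c(WDLPS = 4L, DDLPS = 0L),
                       n_tumor = c(WDLPS = 6L, DDLPS = 7L),
                       n_normal = 13L,
                       sigmoid_midpoint = 5,
                       midpoint_spread = 5,
                       sigmoid_slope = 2,
                       program_amplitude = 10,
                       malignancy_n = 100L,
                       malignancy_effect = 1,
                       normal_signature_n = 500L,
                       normal_signature_effect = 0,
                       noise_sd = 0.3,
                       batch_shift = 2,
                       batch_scale = 1.5,
                       lipid_classes = c("TG", "DG", "PC", "PE", "LPE",
                                         "LPC", "SM", "ChE", "Cer", "Hex1Cer"),
                       species_per_class = 20L,
                       class_log2_effects = c(TG = 1.5, DG = 1.5, PC = -1.5,
                                              PE = -1.5, SM = -1.5, ChE = -1),
                       lipid_groups = c(WDLPS = 6L, DDLPS = 7L),
                       lipid_dispersion = 0.5,
                       count_mode = FALSE,
                       uppercase_fraction = 0) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_program_genes = as.integer(n_program_genes),
              days = as.integer(days),
              svf_replicates = as.integer(svf_replicates),
              stage_assignment = stage_assignment, n_tumor = n_tumor,
              n_normal = as.integer(n_normal),
              sigmoid_midpoint = sigmoid_midpoint,
              midpoint_spread = midpoint_spread,
              sigmoid_slope = sigmoid_slope,
              program_amplitude = program_amplitude,
              malignancy_n = as.integer(malignancy_n),
              malignancy_effect = malignancy_effect,
              normal_signature_n = as.integer(normal_signature_n),
              normal_signature_effect = normal_signature_effect,
              noise_sd = noise_sd, batch_shift = batch_shift,
              batch_scale = batch_scale, lipid_classes = lipid_classes,
              species_per_class = as.integer(species_per_class),
              class_log2_effects = class_log2_effects,
              lipid_groups = lipid_groups,
              lipid_dispersion = lipid_dispersion,
              count_mode = isTRUE(count_mode),
              uppercase_fraction = uppercase_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_program_genes > 0,
            cfg$n_program_genes <= cfg$n_genes,
            length(cfg$days) >= 2, !is.unsorted(cfg$days, strictly = TRUE),
            cfg$svf_replicates > 0, all(cfg$n_tumor > 0), cfg$n_normal > 0,
            all(is.finite(unlist(cfg[c("sigmoid_midpoint", "sigmoid_slope",
                                       "program_amplitude", "malignancy_effect",
                                       "noise_sd", "batch_shift", "batch_scale",
                                       "lipid_dispersion")]))),
            cfg$noise_sd >= 0, cfg$batch_scale > 0,
            cfg$malignancy_n <= cfg$n_genes,
            cfg$normal_signature_n <= cfg$n_genes,
            cfg$midpoint_spread >= 0,
            cfg$species_per_class > 0, all(cfg$lipid_groups >= 2),
            length(cfg$lipid_groups) == 2,
            cfg$uppercase_fraction >= 0, cfg$uppercase_fraction <= 1)
  if (is.null(names(cfg$stage_assignment)) ||
      !setequal(names(cfg$stage_assignment), names(cfg$n_tumor))) {
    stop("stage_assignment and n_tumor must name the same tumor groups")
  }
  bad <- setdiff(cfg$stage_assignment, cfg$days)
  if (length(bad)) {
    stop("stage assigned to day(s) not in the time course: ",
         paste(bad, collapse = ", "))
  }
  unknown <- setdiff(names(cfg$class_log2_effects), cfg$lipid_classes)
  if (length(unknown)) {
    stop("class_log2_effects for unsimulated class(es): ",
         paste(unknown, collapse = ", "))
  }
  invisible(cfg)
}

sigmoid_trajectory <- function(amplitude, day, midpoint, slope) {
  amplitude / (1 + exp(-slope * (day - midpoint)))
}

#' Simulate tumor / normal / time-course expression with ground truth
#'
#' Generates one expression matrix containing the full staged design:
#' program genes follow a monotone sigmoid over the differentiation days;
#' time-course (SVF) samples are the day trajectory plus noise; each tumor
#' group is its assigned day's trajectory plus a shared malignancy
#' signature plus noise; normal samples follow the mature (post-time-course
#' asymptote) profile. Tissue samples (tumor + normal) and cell-culture
#' samples (time course) form two batches; the culture batch receives the
#' configured additive shift on every gene and its noise is scaled by the
#' configured factor. Expression is emitted directly on the log2 scale
#' (or as Poisson-lognormal counts in `count_mode`).
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a [feature_matrix()]; groups are the tumor
#'   group names, `"normal"`, and `"SVF"`; batches `"tissue"` and
#'   `"culture"`; SVF samples carry `day`) and `truth`, a `GroundTruth`
#'   list recording program genes and their per-day trajectory values,
#'   malignancy genes and effects, planted batch effects, and the stage
#'   assignment.
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 2)
  names(baseline) <- genes

  program <- sort(sample.int(cfg$n_genes, cfg$n_program_genes))
  amp <- stats::runif(cfg$n_program_genes, 1, cfg$program_amplitude) *
    sample(c(-1, 1), cfg$n_program_genes, replace = TRUE)
  midpoints <- stats::runif(cfg$n_program_genes,
                            cfg$sigmoid_midpoint - cfg$midpoint_spread,
                            cfg$sigmoid_midpoint + cfg$midpoint_spread)
  mature_day <- max(cfg$days) + 4  # asymptote proxy for fully mature tissue
  traj_days <- c(cfg$days, mature_day)
  traj <- vapply(traj_days, function(d) {
    sigmoid_trajectory(amp, d, midpoints, cfg$sigmoid_slope)
  }, numeric(cfg$n_program_genes))
  dimnames(traj) <- list(genes[program], paste0("day", traj_days))

  malig <- sort(sample.int(cfg$n_genes, cfg$malignancy_n))
  malig_eff <- cfg$malignancy_effect *
    sample(c(-1, 1), cfg$malignancy_n, replace = TRUE)
  norm_sig <- sort(sample.int(cfg$n_genes, cfg$normal_signature_n))
  norm_eff <- cfg$normal_signature_effect *
    sample(c(-1, 1), cfg$normal_signature_n, replace = TRUE)

  day_profile <- function(d) {
    mu <- baseline
    mu[program] <- mu[program] +
      sigmoid_trajectory(amp, d, midpoints, cfg$sigmoid_slope)
    mu
  }
  tumor_profile <- function(d) {
    mu <- day_profile(d)
    mu[malig] <- mu[malig] + malig_eff
    mu
  }
  normal_profile <- function() {
    mu <- day_profile(mature_day)
    mu[norm_sig] <- mu[norm_sig] + norm_eff
    mu
  }

  cols <- list(); meta <- list()
  add_samples <- function(prefix, n, mu, group, batch, day = NA_integer_) {
    sd <- cfg$noise_sd * if (batch == "culture") cfg$batch_scale else 1
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", prefix, i)
      v <- mu + stats::rnorm(cfg$n_genes, 0, sd)
      if (batch == "culture") v <- v + cfg$batch_shift
      cols[[id]] <<- v
      meta[[id]] <<- data.frame(sample_id = id, group = group, batch = batch,
                                day = day, stringsAsFactors = FALSE)
    }
  }
  for (g in names(cfg$n_tumor)) {
    add_samples(g, cfg$n_tumor[[g]],
                tumor_profile(cfg$stage_assignment[[g]]), g, "tissue")
  }
  add_samples("normal", cfg$n_normal, normal_profile(), "normal", "tissue")
  for (d in cfg$days) {
    add_samples(sprintf("SVF_d%02d", d), cfg$svf_replicates,
                day_profile(d), "SVF", "culture", day = d)
  }

  values <- do.call(cbind, cols)
  rownames(values) <- genes
  if (cfg$count_mode) {
    values <- matrix(stats::rpois(length(values), lambda = 2^values),
                     nrow = nrow(values), dimnames = dimnames(values))
    storage.mode(values) <- "double"
  }
  fm <- feature_matrix(values, do.call(rbind, meta))

  # split raw "exports" with style-drifted culture gene labels, for testing
  # the case-insensitive symbol harmonisation (merge_by_symbol)
  upgenes <- integer()
  parts <- NULL
  if (cfg$uppercase_fraction > 0) {
    n_up <- round(cfg$uppercase_fraction * cfg$n_genes)
    upgenes <- sort(sample.int(cfg$n_genes, n_up))
    tissue_idx <- fm$metadata$batch == "tissue"
    culture <- fm$values[, !tissue_idx, drop = FALSE]
    rn <- rownames(culture)
    rn[upgenes] <- toupper(rn[upgenes])
    rownames(culture) <- rn
    parts <- list(
      tissue = feature_matrix(fm$values[, tissue_idx, drop = FALSE],
                              fm$metadata[tissue_idx, , drop = FALSE]),
      culture = feature_matrix(culture,
                               fm$metadata[!tissue_idx, , drop = FALSE]))
  }
  truth <- structure(list(
    program_genes = genes[program],
    program_amplitude = stats::setNames(amp, genes[program]),
    program_midpoints = stats::setNames(midpoints, genes[program]),
    trajectory = traj,
    mature_day = mature_day,
    malignancy_genes = genes[malig],
    malignancy_effects = stats::setNames(malig_eff, genes[malig]),
    normal_signature_genes = if (cfg$normal_signature_effect != 0)
      genes[norm_sig] else character(),
    normal_signature_effects = if (cfg$normal_signature_effect != 0)
      stats::setNames(norm_eff, genes[norm_sig]) else numeric(),
    batch_effects = list(culture = list(shift = cfg$batch_shift,
                                        scale = cfg$batch_scale),
                         tissue = list(shift = 0, scale = 1)),
    stage_assignment = cfg$stage_assignment,
    uppercased_genes = genes[upgenes],
    baseline = baseline
  ), class = "GroundTruth")
  out <- list(matrix = fm, truth = truth)
  if (!is.null(parts)) out$parts <- parts
  out
}

# Draw one grammar-valid shorthand name for a class; exercises multi-chain,
# summed-composition, ether, and sphingoid forms.
random_species_name <- function(class) {
  sphingoid <- class %in% c("SM", "Cer", "Hex1Cer")
  n_chain <- switch(class, TG = 3L, DG = 2L, PC = 2L, PE = 2L,
                    SM = 2L, Cer = 2L, Hex1Cer = 2L, LPC = 1L, LPE = 1L, 2L)
  summed <- stats::runif(1) < 0.3 || n_chain == 1L
  ether_ok <- class %in% c("TG", "DG", "PC", "PE", "LPC", "LPE")
  mk_chain <- function(first) {
    c_n <- sample(seq(12L, 22L, by = 1L), 1)
    db <- sample(0:6, 1)
    pre <- if (sphingoid && first) "d" else ""
    eth <- if (ether_ok && stats::runif(1) < 0.25) "e" else ""
    paste0(pre, c_n, ":", db, eth)
  }
  body <- if (summed) {
    c_n <- sample(seq(28L, 58L, by = 1L), 1)
    db <- sample(0:8, 1)
    pre <- if (sphingoid) "d" else ""
    eth <- if (ether_ok && stats::runif(1) < 0.25) "e" else ""
    paste0(pre, c_n, ":", db, eth)
  } else {
    paste(vapply(seq_len(n_chain), function(i) mk_chain(i == 1L), ""),
          collapse = "/")
  }
  paste0(class, "(", body, ")")
}

#' Simulate a species-level lipidomics table with ground truth
#'
#' Generates grammar-valid shorthand species names for each configured
#' lipid class and log-normal abundances around per-class means, planting
#' the configured per-class log2 group effect (group A over group B,
#' applied symmetrically as +/- half the effect). All emitted names parse
#' with [parse_lipid_name()].
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a [feature_matrix()] of raw abundances,
#'   species x samples) and `truth` (`GroundTruth` list: per-species class,
#'   planted log2 effect and differential flag, per-class effects).
#' @export
simulate_lipidomics <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 1L)  # independent stream from the expression draw
  classes <- cfg$lipid_classes
  effects <- stats::setNames(rep(0, length(classes)), classes)
  effects[names(cfg$class_log2_effects)] <- cfg$class_log2_effects

  names_all <- character(0)
  class_all <- character(0)
  for (cl in classes) {
    nm <- character(0)
    while (length(nm) < cfg$species_per_class) {
      cand <- random_species_name(cl)
      if (!cand %in% c(nm, names_all)) nm <- c(nm, cand)
    }
    names_all <- c(names_all, nm)
    class_all <- c(class_all, rep(cl, cfg$species_per_class))
  }

  g_a <- names(cfg$lipid_groups)[1]
  g_b <- names(cfg$lipid_groups)[2]
  n_a <- cfg$lipid_groups[[1]]
  n_b <- cfg$lipid_groups[[2]]
  sample_ids <- c(sprintf("%s_L%02d", g_a, seq_len(n_a)),
                  sprintf("%s_L%02d", g_b, seq_len(n_b)))
  groups <- c(rep(g_a, n_a), rep(g_b, n_b))

  class_base <- stats::setNames(stats::runif(length(classes), 12, 18), classes)
  species_off <- stats::rnorm(length(names_all), 0, 1)
  eff <- effects[class_all]
  log2_mu <- class_base[class_all] + species_off
  shift <- ifelse(groups == g_a, +0.5, -0.5)
  log2_vals <- outer(log2_mu, rep(1, length(sample_ids))) +
    outer(eff, shift) +
    matrix(stats::rnorm(length(names_all) * length(sample_ids),
                        0, cfg$lipid_dispersion),
           nrow = length(names_all))
  values <- 2^log2_vals
  dimnames(values) <- list(names_all, sample_ids)

  fm <- feature_matrix(values, data.frame(sample_id = sample_ids,
                                          group = groups,
                                          stringsAsFactors = FALSE))
  truth <- structure(list(
    species_class = stats::setNames(class_all, names_all),
    class_effects = effects,
    species_log2_effect = stats::setNames(unname(eff), names_all),
    differential = stats::setNames(unname(eff) != 0, names_all),
    group_a = g_a, group_b = g_b
  ), class = "GroundTruth")
  list(matrix = fm, truth = truth)
}
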