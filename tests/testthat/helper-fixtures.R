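# Shared fixtures built in code.

# All shorthand species names printed in the study's differential-lipid
# discussion; the golden round-trip suite.
golden_species_names <- c(
  "DG(16:0/14:0)", "DG(16:1/14:0)", "TG(16:0e/6:0/10:1)",
  "TG(20:1/18:1/18:3)", "DG(30:3e)", "TG(16:1/14:0/18:2)",
  "TG(16:0/16:1/18:3)", "DG(38:2e)",
  "PC(34:2e)", "PC(32:0e)", "Hex1Cer(d18:0/20:4)", "PC(40:4)",
  "PC(16:1e/20:4)", "PC(18:2e/20:4)", "PC(38:6e)", "LPE(18:1e)",
  "PC(14:1e/20:4)")

# Minimal two-group abundance matrix with hand-set values.
tiny_lipid_matrix <- function(values, groups = c("A", "A", "B", "B")) {
  m <- matrix(values, nrow = length(values) / length(groups),
              byrow = TRUE)
  rownames(m) <- paste0("TG(", 48 + seq_len(nrow(m)), ":2)")
  colnames(m) <- paste0("s", seq_along(groups))
  feature_matrix(m, data.frame(sample_id = colnames(m), group = groups,
                               stringsAsFactors = FALSE))
}

# Expression-like matrix with explicit batch labels, Gaussian values.
two_batch_matrix <- function(n_genes = 50, n_per_batch = c(10, 10),
                             shift = 0, scale = 1, seed = 42) {
  set.seed(seed)
  n <- sum(n_per_batch)
  base <- rnorm(n_genes, 8, 2)
  vals <- base + matrix(rnorm(n_genes * n, 0, 0.5), n_genes, n)
  b2 <- seq_len(n) > n_per_batch[1]
  vals[, b2] <- base + shift +
    matrix(rnorm(n_genes * sum(b2), 0, 0.5 * scale), n_genes, sum(b2))
  dimnames(vals) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n)))
  feature_matrix(vals, data.frame(
    sample_id = colnames(vals),
    group = "all",
    batch = ifelse(b2, "B", "A"),
    stringsAsFactors = FALSE))
}

# Deterministic ranked list for enrichment tests.
toy_ranked <- function(n = 20, seed = 5) {
  set.seed(seed)
  scores <- sort(rnorm(n, 0, 2), decreasing = TRUE)
  names(scores) <- sprintf("G%02d", seq_len(n))
  scores
}

write_gmt_fixture <- function(path, sets) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, paste0(id, " synthetic set"), sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  path
}
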