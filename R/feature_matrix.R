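#' Feature-by-sample matrix with sample metadata
#'
#' `feature_matrix()` is the container every pipeline stage consumes and
#' returns: a numeric matrix of features (lipid species, lipid classes, or
#' genes) by samples, plus per-sample metadata carrying at least a `group`
#' label and optionally a `batch` label and an integer `day` (for
#' differentiation time-course samples).
#'
#' @param values numeric matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids).
#' @param metadata `data.frame` with one row per sample. Must contain a
#'   `sample_id` column matching `colnames(values)` and a `group` column;
#'   `batch` and `day` columns are optional. Rows are reordered to match the
#'   column order of `values`.
#' @return An object of class `"FeatureMatrix"`: a list with elements
#'   `values` and `metadata`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' fm <- feature_matrix(m, data.frame(sample_id = colnames(m),
#'                                    group = c("A", "A", "B")))
#' dim(fm)
#' @export
feature_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have rownames (feature ids) and colnames (sample ids)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    stop("metadata must contain 'sample_id' and 'group' columns")
  }
  if (!setequal(metadata$sample_id, colnames(values)) ||
      nrow(metadata) != ncol(values)) {
    stop("metadata sample_ids must match colnames(values) exactly")
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (anyNA(metadata$group)) stop("every sample needs a group label")
  structure(list(values = values, metadata = metadata), class = "FeatureMatrix")
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$values)

#' @export
dimnames.FeatureMatrix <- function(x) dimnames(x$values)

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  grp <- table(x$metadata$group)
  cat("groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
  if (!is.null(x$metadata$batch)) {
    bt <- table(x$metadata$batch)
    cat("batches:", paste(sprintf("%s (%d)", names(bt), bt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a FeatureMatrix
#'
#' @param x a [feature_matrix()].
#' @param i feature index (logical, integer, or character).
#' @param j sample index (logical, integer, or character).
#' @param ... ignored.
#' @return A `FeatureMatrix` restricted to the selected features/samples.
#' @export
`[.FeatureMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  feature_matrix(v, x$metadata[match(colnames(v), x$metadata$sample_id), ,
                               drop = FALSE])
}

#' Sample ids belonging to a group label
#' @param fm a [feature_matrix()].
#' @param group group label to select.
#' @return character vector of sample ids.
#' @export
samples_in_group <- function(fm, group) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  fm$metadata$sample_id[fm$metadata$group %in% group]
}

#' Read a feature table and sample sheet from delimited text
#'
#' The feature table has feature ids in the first column and one column per
#' sample; the sample sheet has one row per sample with `sample_id`, `group`
#' and optional `batch`/`day` columns. Tabs are the default separator; a
#' comma separator is autodetected from the header line.
#'
#' @param table_path path to the feature table (TSV/CSV).
#' @param meta_path path to the sample sheet (TSV/CSV).
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(table_path, meta_path) {
  tab <- read_delim_auto(table_path)
  if (ncol(tab) < 2) stop("feature table needs >=1 sample column")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(tab[[1]])
  meta <- read_delim_auto(meta_path)
  feature_matrix(vals, meta)
}

#' Write a FeatureMatrix (or plain matrix) as TSV
#' @param fm a [feature_matrix()] or numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name for the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path, id_col = "feature_id") {
  v <- if (inherits(fm, "FeatureMatrix")) fm$values else fm
  df <- data.frame(rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Sniff comma vs tab from the header line.
read_delim_auto <- function(path) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path)) {
    stop("file not found: '", path, "'")
  }
  header <- readLines(path, n = 1L)
  sep <- if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}
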