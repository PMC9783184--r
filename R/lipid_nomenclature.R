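#' Default lipid class registry
#'
#' The parser only accepts class tokens present in a registry mapping the
#' shorthand token to a display name. The default covers the classes that
#' dominate adipocytic tissue lipidomes (neutral storage lipids, membrane
#' phospholipids, sphingolipids) plus their lyso- forms. Tokens are matched
#' case-sensitively.
#'
#' Note on "ChE": vendor software commonly prints "ChE" while labelling the
#' class "cholesterol", although the abbreviation conventionally denotes
#' cholesteryl esters; the registry keeps both readings in the display name
#' rather than silently picking one.
#'
#' @return Named character vector: shorthand token -> display name.
#' @examples
#' default_lipid_registry()[c("TG", "PC")]
#' @export
default_lipid_registry <- function() {
  c(TG      = "triacylglycerol",
    DG      = "diacylglycerol",
    PC      = "phosphatidylcholine",
    PE      = "phosphatidylethanolamine",
    LPC     = "lysophosphatidylcholine",
    LPE     = "lysophosphatidylethanolamine",
    SM      = "sphingomyelin",
    ChE     = "cholesterol / cholesteryl ester (ambiguous vendor shorthand)",
    Cer     = "ceramide",
    Hex1Cer = "monohexosylceramide")
}

lipid_parse_error <- function(msg, token, offset) {
  stop(errorCondition(
    sprintf("%s (token '%s' at character %d)", msg, token, offset),
    token = token, offset = offset,
    class = c("lipid_parse_error", "error", "condition")))
}

#' Parse one shorthand lipid species name
#'
#' Understands the flat shorthand convention used by untargeted lipidomics
#' software: a class token followed by a parenthesised composition, either
#' chain-resolved with "/"-separated acyl chains (`"TG(16:0/16:1/18:3)"`,
#' `"DG(16:0/14:0)"`) or as a summed composition (`"PC(34:2)"`). Each chain
#' token is `carbons:double_bonds`, optionally prefixed by a sphingoid-base
#' hydroxylation code (`"d"`/`"t"`, as in `"Hex1Cer(d18:0/20:4)"`) and
#' optionally suffixed by `"e"` marking an ether-linked chain
#' (`"PC(16:1e/20:4)"`, `"DG(30:3e)"`). sn-position and stereochemistry are
#' outside this grammar.
#'
#' @param name a single species name. Leading/trailing whitespace is
#'   stripped; the class token is matched case-sensitively against
#'   `registry`.
#' @param registry named character vector of accepted class tokens, see
#'   [default_lipid_registry()].
#' @return A `LipidSpecies` object: list with `raw_name`, `lipid_class`,
#'   `class_name`, `total_carbons`, `total_double_bonds`, `ether_linked`,
#'   `sphingoid_prefix` (`NA` if absent) and `chains`, a data.frame with
#'   columns `carbons`, `double_bonds`, `ether`, `prefix` (zero rows for a
#'   summed composition).
#' @seealso [format.LipidSpecies()] for the inverse (serialisation).
#' @examples
#' sp <- parse_lipid_name("TG(16:0e/6:0/10:1)")
#' sp$total_carbons       # 32
#' sp$ether_linked        # TRUE
#' format(parse_lipid_name("Hex1Cer(d18:0/20:4)"))
#' @export
parse_lipid_name <- function(name, registry = default_lipid_registry()) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(trimws(name))) {
    stop("'name' must be a single non-empty string")
  }
  raw <- trimws(name)
  open <- regexpr("(", raw, fixed = TRUE)
  if (open < 0L) lipid_parse_error("missing '('", raw, nchar(raw))
  if (substr(raw, nchar(raw), nchar(raw)) != ")") {
    lipid_parse_error("unbalanced parentheses", raw, nchar(raw))
  }
  cls <- substr(raw, 1L, open - 1L)
  if (!cls %in% names(registry)) {
    lipid_parse_error("unknown class token", if (nzchar(cls)) cls else raw, 1L)
  }
  body <- substr(raw, open + 1L, nchar(raw) - 1L)
  if (grepl("[()]", body)) {
    lipid_parse_error("unbalanced parentheses", body, open + 1L)
  }
  if (!nzchar(body)) lipid_parse_error("empty composition", raw, open + 1L)

  tokens <- strsplit(body, "/", fixed = TRUE)[[1]]
  # character offset of each token within the full (trimmed) name
  offs <- open + 1L + cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)]
  chain_re <- "^([dt]?)([0-9]+):([0-9]+)(e?)$"
  parsed <- lapply(seq_along(tokens), function(i) {
    tok <- tokens[[i]]
    m <- regmatches(tok, regexec(chain_re, tok))[[1]]
    if (length(m) == 0L) {
      lipid_parse_error("malformed chain token", tok, offs[[i]])
    }
    list(prefix = m[[2]], carbons = as.integer(m[[3]]),
         double_bonds = as.integer(m[[4]]), ether = m[[5]] == "e")
  })

  prefix <- vapply(parsed, `[[`, "", "prefix")
  carbons <- vapply(parsed, `[[`, 0L, "carbons")
  dbl <- vapply(parsed, `[[`, 0L, "double_bonds")
  ether <- vapply(parsed, `[[`, FALSE, "ether")

  summed <- length(tokens) == 1L
  chains <- if (summed) {
    data.frame(carbons = integer(), double_bonds = integer(),
               ether = logical(), prefix = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(carbons = carbons, double_bonds = dbl, ether = ether,
               prefix = prefix, stringsAsFactors = FALSE)
  }
  structure(list(
    raw_name = raw,
    lipid_class = cls,
    class_name = unname(registry[[cls]]),
    total_carbons = sum(carbons),
    total_double_bonds = sum(dbl),
    ether_linked = any(ether),
    sphingoid_prefix = if (any(nzchar(prefix))) prefix[nzchar(prefix)][[1]] else NA_character_,
    chains = chains
  ), class = "LipidSpecies")
}

#' @export
print.LipidSpecies <- function(x, ...) {
  cat(sprintf("<LipidSpecies> %s: %s %d:%d%s%s, %s\n",
              x$raw_name, x$class_name, x$total_carbons, x$total_double_bonds,
              if (x$ether_linked) " ether-linked" else "",
              if (!is.na(x$sphingoid_prefix))
                paste0(" sphingoid '", x$sphingoid_prefix, "'") else "",
              if (nrow(x$chains)) paste(nrow(x$chains), "chains")
              else "summed composition"))
  invisible(x)
}

#' Serialise a LipidSpecies back to shorthand
#'
#' Inverse of [parse_lipid_name()]: `format(parse_lipid_name(x))` equals
#' `x` up to surrounding whitespace.
#'
#' @param x a `LipidSpecies`.
#' @param ... ignored.
#' @return The shorthand name as a single string.
#' @export
format.LipidSpecies <- function(x, ...) {
  body <- if (nrow(x$chains) == 0L) {
    paste0(if (!is.na(x$sphingoid_prefix)) x$sphingoid_prefix else "",
           x$total_carbons, ":", x$total_double_bonds,
           if (x$ether_linked) "e" else "")
  } else {
    paste(vapply(seq_len(nrow(x$chains)), function(i) {
      ch <- x$chains[i, ]
      paste0(ch$prefix, ch$carbons, ":", ch$double_bonds,
             if (ch$ether) "e" else "")
    }, ""), collapse = "/")
  }
  paste0(x$lipid_class, "(", body, ")")
}

#' Parse a vector of species names into a summary table
#'
#' @param names character vector of shorthand species names.
#' @param registry class registry, see [default_lipid_registry()].
#' @param strict if `TRUE`, any unparseable name is an error; otherwise
#'   unparseable names get `NA` fields and a single summarising warning.
#' @return data.frame with one row per input name: `raw_name`,
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `ether_linked`,
#'   `sphingoid_prefix`, `n_chains`, `parsed` (logical), `error` (message or
#'   `NA`).
#' @export
parse_lipid_table <- function(names, registry = default_lipid_registry(),
                              strict = FALSE) {
  rows <- lapply(names, function(nm) {
    sp <- tryCatch(parse_lipid_name(nm, registry), lipid_parse_error = identity)
    if (inherits(sp, "condition")) {
      if (strict) stop(sp)
      data.frame(raw_name = nm, lipid_class = NA_character_,
                 total_carbons = NA_integer_, total_double_bonds = NA_integer_,
                 ether_linked = NA, sphingoid_prefix = NA_character_,
                 n_chains = NA_integer_, parsed = FALSE,
                 error = conditionMessage(sp), stringsAsFactors = FALSE)
    } else {
      data.frame(raw_name = nm, lipid_class = sp$lipid_class,
                 total_carbons = sp$total_carbons,
                 total_double_bonds = sp$total_double_bonds,
                 ether_linked = sp$ether_linked,
                 sphingoid_prefix = sp$sphingoid_prefix,
                 n_chains = nrow(sp$chains), parsed = TRUE,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!strict && any(!out$parsed)) {
    warning(sum(!out$parsed), " of ", nrow(out),
            " species names failed to parse and were flagged")
  }
  out
}

#' Aggregate a species-level lipid table to lipid classes
#'
#' Sums the abundance of all species of the same class within each sample
#' (the per-class totals behind a stacked composition plot). In fraction
#' mode each sample's class abundances are divided by their total so that
#' the per-sample fractions sum to one.
#'
#' @param fm a [feature_matrix()] whose feature ids are shorthand species
#'   names.
#' @param mode `"absolute"` (summed abundances, default) or `"fraction"`
#'   (per-sample class fractions).
#' @param registry class registry, see [default_lipid_registry()].
#' @param strict if `TRUE`, an unparseable species name aborts the run;
#'   by default such rows are dropped with a warning.
#' @return A `FeatureMatrix` with one row per lipid class present.
#' @examples
#' fm <- simulate_lipidomics(sim_config(seed = 1))$matrix
#' comp <- aggregate_by_class(fm, mode = "fraction")
#' colSums(comp$values)   # all 1
#' @export
aggregate_by_class <- function(fm, mode = c("absolute", "fraction"),
                               registry = default_lipid_registry(),
                               strict = FALSE) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  mode <- match.arg(mode)
  parsed <- parse_lipid_table(rownames(fm$values), registry, strict = strict)
  keep <- parsed$parsed
  if (!any(keep)) stop("no species name parsed; cannot aggregate")
  vals <- fm$values[keep, , drop = FALSE]
  cls <- parsed$lipid_class[keep]
  agg <- rowsum(vals, group = cls, reorder = TRUE)
  if (mode == "fraction") {
    tot <- colSums(agg)
    if (any(tot <= 0)) stop("sample with non-positive total abundance")
    agg <- sweep(agg, 2L, tot, "/")
  }
  feature_matrix(agg, fm$metadata)
}
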