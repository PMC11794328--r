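# TSV schemas: required columns, numeric columns, ID validators
TABLE_SCHEMAS <- list(
  disease_gene = list(cols = c("disease_id", "gene_id")),
  disease_phenotype = list(cols = c("disease_id", "hpo_id"),
                           validate = "hpo_id"),
  gene_funfam = list(cols = c("gene_id", "funfam_id"),
                     validate = "funfam_id"),
  drug_target = list(cols = c("drug_id", "target_id")),
  gold = list(cols = c("hpo_id", "drug_id"), validate = "hpo_id"),
  activities = list(cols = c("drug_id", "target_id", "therapeutic_flag",
                             "assay_type", "relationship_type",
                             "target_type", "pchembl"),
                    numeric = c("therapeutic_flag", "pchembl")),
  comentions = list(cols = c("drug_id", "hpo_id", "n_drug", "n_hpo",
                             "n_both", "n_total"),
                    numeric = c("n_drug", "n_hpo", "n_both", "n_total"),
                    validate = "hpo_id"),
  pairs = list(cols = c("a_id", "b_id", "k", "size_a", "size_b", "n_pop",
                        "p_value", "hyi"),
               numeric = c("k", "size_a", "size_b", "n_pop", "p_value",
                           "hyi"))
)

# roles attached when an edge schema is turned into bipartite_edges
EDGE_ROLES <- list(
  disease_gene = c(outer = "gene", middle = "disease"),
  disease_phenotype = c(outer = "phenotype", middle = "disease"),
  gene_funfam = c(outer = "gene", middle = "funfam"),
  drug_target = c(outer = "drug", middle = "target")
)

#' Read a validated input table
#'
#' Reads a tab-separated table (plain or gzip-compressed; `#` lines are
#' comments), checks the header against the named schema, validates ID
#' formats, and reports malformed rows with their file line numbers.
#'
#' @param path File path (`.gz` accepted).
#' @param schema One of `"disease_gene"`, `"disease_phenotype"`,
#'   `"gene_funfam"`, `"drug_target"`, `"gold"`, `"activities"`,
#'   `"comentions"`, `"pairs"`.
#' @return A tibble with the schema's columns.
#' @export
read_input <- function(path, schema) {
  if (!schema %in% names(TABLE_SCHEMAS)) {
    abort_argument(paste0("unknown schema: ", schema))
  }
  spec <- TABLE_SCHEMAS[[schema]]
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  content_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(content_idx) == 0) {
    abort_format(sprintf("%s: no header line found", path))
  }
  header_line <- content_idx[1]
  header <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(spec$cols, header)
  if (length(missing_cols) > 0) {
    abort_format(sprintf("%s: missing required column(s): %s", path,
                         paste(missing_cols, collapse = ", ")))
  }
  data_idx <- content_idx[-1]
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad_rows <- data_idx[n_fields != length(header)]
  if (length(bad_rows) > 0) {
    abort_format(sprintf("%s: malformed row(s) at line(s) %s", path,
                         paste(head(bad_rows, 5), collapse = ", ")))
  }
  tbl <- as_tibble(setNames(
    lapply(seq_along(header), function(j) {
      vapply(fields, `[[`, character(1), j)
    }), header))
  for (col in spec$numeric %||% character()) {
    val <- suppressWarnings(as.numeric(ifelse(tbl[[col]] %in% c("", "NA"),
                                              NA, tbl[[col]])))
    bad <- which(!is.na(tbl[[col]]) & !(tbl[[col]] %in% c("", "NA")) &
                   is.na(val))
    if (length(bad) > 0) {
      abort_format(sprintf("%s: non-numeric %s at line(s) %s", path, col,
                           paste(head(data_idx[bad], 5), collapse = ", ")))
    }
    tbl[[col]] <- val
  }
  for (col in spec$validate %||% character()) {
    pattern <- ID_PATTERNS[[col]]
    bad <- which(!stringr::str_detect(tbl[[col]], pattern))
    if (length(bad) > 0) {
      abort_format(sprintf("%s: malformed %s at line(s) %s", path, col,
                           paste(head(data_idx[bad], 5), collapse = ", ")))
    }
  }
  tbl[spec$cols]
}

#' Read an edge-list table as bipartite edges
#'
#' @inheritParams read_input
#' @param schema One of the edge schemas (`"disease_gene"`,
#'   `"disease_phenotype"`, `"gene_funfam"`, `"drug_target"`).
#' @return A `bipartite_edges` object with the schema's role labels.
#' @export
read_edges <- function(path, schema) {
  if (!schema %in% names(EDGE_ROLES)) {
    abort_argument(paste0("not an edge schema: ", schema))
  }
  tbl <- read_input(path, schema)
  roles <- EDGE_ROLES[[schema]]
  cols <- TABLE_SCHEMAS[[schema]]$cols
  # column 2 is the outer entity for annotation tables keyed by disease,
  # column 1 otherwise
  if (schema %in% c("disease_gene", "disease_phenotype")) {
    bipartite_edges(tbl, outer = cols[2], middle = cols[1],
                    outer_role = unname(roles["outer"]),
                    middle_role = unname(roles["middle"]))
  } else {
    bipartite_edges(tbl, outer = cols[1], middle = cols[2],
                    outer_role = unname(roles["outer"]),
                    middle_role = unname(roles["middle"]))
  }
}

provenance_lines <- function(parameters = list(), inputs = NULL,
                             seed = NULL) {
  lines <- sprintf("# phenodrug %s", as.character(packageVersion("phenodrug")))
  if (length(parameters) > 0) {
    kv <- paste(names(parameters), vapply(parameters, format, character(1)),
                sep = "=", collapse = " ")
    lines <- c(lines, paste0("# parameters: ", kv))
  }
  if (!is.null(inputs)) {
    digests <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("# input %s: %s", names(inputs),
                              unname(digests)))
  }
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", seed))
  lines
}

write_table <- function(df, path, comments = character()) {
  body <- readr::format_tsv(df)
  readr::write_lines(c(comments, sub("\n$", "", body)), path)
  invisible(path)
}

#' Write scored pairs to TSV
#'
#' Deterministic, diff-able output: `#` provenance comment lines (tool
#' version, parameters, input digests, seed - never timestamps) followed
#' by the pair table with round-trippable number formatting.
#'
#' @param pairs An `hyi_pairs` tibble.
#' @param path Output path.
#' @param parameters Named list recorded in the provenance header.
#' @param inputs Optional named character vector of input file paths whose
#'   md5 digests are recorded.
#' @param seed Optional integer recorded in the provenance header.
#' @return The path, invisibly.
#' @export
write_pairs <- function(pairs, path, parameters = list(), inputs = NULL,
                        seed = NULL) {
  if (!is_hyi_pairs(pairs)) abort_argument("`pairs` must be an hyi_pairs object")
  thr <- attr(pairs, "threshold_applied")
  meta <- c(provenance_lines(parameters, inputs, seed),
            sprintf("# a_role: %s", attr(pairs, "a_role") %||% "a"),
            sprintf("# b_role: %s", attr(pairs, "b_role") %||% "b"),
            if (!is.na(thr %||% NA_real_))
              sprintf("# threshold_applied: %s", format(thr)))
  write_table(as_tibble(pairs), path, meta)
}

#' Read scored pairs written by [write_pairs()]
#'
#' @param path File path.
#' @return An `hyi_pairs` tibble; the roles and applied threshold are
#'   restored from the provenance header.
#' @export
read_pairs <- function(path) {
  lines <- readr::read_lines(path, n_max = 50L)
  comment <- lines[startsWith(lines, "#")]
  grab <- function(key) {
    hit <- comment[startsWith(comment, paste0("# ", key, ":"))]
    if (length(hit) == 0) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  tbl <- read_input(path, "pairs")
  thr <- suppressWarnings(as.numeric(grab("threshold_applied")))
  new_hyi_pairs(tbl,
                a_role = grab("a_role") %|NA|% "a",
                b_role = grab("b_role") %|NA|% "b",
                threshold_applied = thr)
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Write a validation report to TSV
#'
#' One row per threshold (and source). An infinite ratio is written as the
#' sentinel string `"inf"`.
#'
#' @param report A `validation_report` tibble.
#' @param path Output path.
#' @param parameters,inputs,seed Provenance header fields (see
#'   [write_pairs()]).
#' @return The path, invisibly.
#' @export
write_validation_report <- function(report, path, parameters = list(),
                                    inputs = NULL, seed = NULL) {
  out <- as_tibble(report)
  out$ratio <- ifelse(is.infinite(out$ratio), "inf",
                      vapply(out$ratio, format, character(1)))
  write_table(out, path, provenance_lines(parameters, inputs, seed))
}

#' Write a synthetic universe to a directory of TSV files
#'
#' Emits every input table plus `planted_manifest.tsv`, the ground truth
#' for scoring recovery.
#'
#' @param universe A `phenodrug_universe` from [generate_universe()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_universe <- function(universe, dir) {
  if (!inherits(universe, "phenodrug_universe")) {
    abort_argument("`universe` must come from generate_universe()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- universe$config
  meta <- provenance_lines(parameters = cfg[setdiff(names(cfg), "seed")],
                           seed = cfg$seed)
  files <- c(disease_gene = "disease_gene.tsv",
             disease_phenotype = "disease_phenotype.tsv",
             gene_funfam = "gene_funfam.tsv",
             activities = "activities.tsv",
             gold = "gold.tsv",
             comentions = "comentions.tsv",
             planted = "planted_manifest.tsv")
  for (nm in names(files)) {
    write_table(universe[[nm]], file.path(dir, files[[nm]]), meta)
  }
  invisible(dir)
}

#' Load a YAML run configuration
#'
#' Settings mirror the command-line flags; explicit flags take precedence
#' when the two are merged.
#'
#' @param path YAML file path.
#' @return A named list of settings.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  cfg <- yaml::read_yaml(path)
  # YAML sequences of mixed int/real scalars arrive as lists; flatten them
  lapply(cfg, function(x) {
    if (is.list(x) && length(x) > 0 &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1,
                   logical(1)))) {
      unlist(x)
    } else {
      x
    }
  })
}
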