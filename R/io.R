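# Plain-text serialization: tab-separated tables for replicate data and
# annotations, aligned TSV matrices plus a JSON sidecar for correlation
# results, JSON for the synthetic truth.

#' Read and write replicate tables
#'
#' Replicate tables are tab-separated text with a header and columns `line`,
#' `group`, `replicate`, `trait`, `value`.
#'
#' @param data Replicate table tibble.
#' @param path File path.
#' @return `write_replicate_table()` returns `path` invisibly;
#'   `read_replicate_table()` returns the tibble.
#' @export
write_replicate_table <- function(data, path) {
  readr::write_tsv(as_tibble(data), path)
  invisible(path)
}

#' @rdname write_replicate_table
#' @export
read_replicate_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    line = readr::col_character(), group = readr::col_character(),
    replicate = readr::col_integer(), trait = readr::col_character(),
    value = readr::col_double()
  ))
}

#' Read and write trait annotations
#'
#' Tab-separated with columns `trait`, `group`, `class`, `subclass`.
#'
#' @param annotation Annotation tibble.
#' @param path File path.
#' @return `write_trait_annotation()` returns `path` invisibly;
#'   `read_trait_annotation()` returns the tibble.
#' @export
write_trait_annotation <- function(annotation, path) {
  readr::write_tsv(as_tibble(annotation), path)
  invisible(path)
}

#' @rdname write_trait_annotation
#' @export
read_trait_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Serialize a correlation result
#'
#' Writes three aligned tab-separated matrices (`<stem>_r.tsv`,
#' `<stem>_p.tsv`, `<stem>_n.tsv`, row names in the first column) and a JSON
#' metadata sidecar `<stem>_meta.json`.
#'
#' @param cr A `cor_result`.
#' @param stem Path stem (without extension).
#' @return `write_cor_result()` returns `stem` invisibly;
#'   `read_cor_result()` returns the `cor_result`.
#' @export
write_cor_result <- function(cr, stem) {
  stopifnot(inherits(cr, "cor_result"))
  write_mat <- function(m, path) {
    df <- data.frame(trait = rownames(m), m, check.names = FALSE)
    readr::write_tsv(df, path)
  }
  write_mat(cr$r, paste0(stem, "_r.tsv"))
  write_mat(cr$p, paste0(stem, "_p.tsv"))
  write_mat(cr$n, paste0(stem, "_n.tsv"))
  jsonlite::write_json(cr$meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_cor_result
#' @export
read_cor_result <- function(stem) {
  read_mat <- function(path) {
    df <- readr::read_tsv(path, col_types = readr::cols(
      trait = readr::col_character(), .default = readr::col_double()))
    m <- as.matrix(df[-1])
    rownames(m) <- df$trait
    m
  }
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  n <- read_mat(paste0(stem, "_n.tsv"))
  storage.mode(n) <- "integer"
  new_cor_result(read_mat(paste0(stem, "_r.tsv")),
                 read_mat(paste0(stem, "_p.tsv")), n,
                 meta$mode, meta$B, meta$seed, meta$min_n, meta$p_adjust)
}

#' Serialize the planted truth of a synthetic population
#'
#' @param truth A `synthetic_truth`.
#' @param path JSON file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    planted_edges = as_tibble(raw$planted_edges),
    null_pairs = as_tibble(raw$null_pairs),
    planted_gene_links = as_tibble(raw$planted_gene_links),
    group_effects = as_tibble(raw$group_effects)
  ), class = "synthetic_truth")
}

#' Write a class-pair summary in the published table layout
#'
#' Classes as rows and columns, integer percent-positive cells, CSV.
#'
#' @param summary A `class_pair_summary`.
#' @param path CSV file path.
#' @param value Statistic to tabulate, see [class_pair_matrix()].
#' @return `path`, invisibly.
#' @export
write_class_pair_table <- function(summary, path, value = "pct_positive") {
  m <- class_pair_matrix(summary, value = value)
  df <- data.frame(class = rownames(m), m, check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}
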