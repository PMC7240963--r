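#' @title Lines-by-traits matrices
#' @description Internal constructor for the `trait_matrix` container: a
#'   numeric lines-by-traits matrix plus a parallel replicate-support matrix
#'   and a per-column transform flag (`"raw"`, `"standardized"`,
#'   `"log_standardized"`).
#' @noRd
new_trait_matrix <- function(values, support, transform) {
  stopifnot(is.matrix(values), identical(dim(values), dim(support)),
            length(transform) == ncol(values))
  structure(list(values = values, support = support,
                 transform = setNames(transform, colnames(values))),
            class = "trait_matrix")
}

#' Average replicate measurements into a lines-by-traits matrix
#'
#' Collapses a long replicate table to one value per (line, trait): the
#' arithmetic mean over that line's replicates, with the number of replicates
#' retained as a support count. Cells with no records are missing. Applying
#' the function to already aggregated data (one replicate everywhere) returns
#' the same values.
#'
#' @param data Data frame with columns `line`, `trait`, `value` (a
#'   `replicate` column, if present, is only used for the uniqueness check;
#'   `group` is ignored here).
#' @return A `trait_matrix` whose columns are flagged `"raw"`.
#' @export
#' @examples
#' d <- data.frame(line = c("L1", "L1"), replicate = 1:2,
#'                 trait = "T1", value = c(2, 4))
#' m <- aggregate_replicates(d)
#' m$values           # 3
#' m$support          # 2
aggregate_replicates <- function(data) {
  data <- as_tibble(data)
  need <- c("line", "trait", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(paste("replicate table lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(data) == 0)
    abort("replicate table is empty; nothing to aggregate",
          class = "traitnet_empty_error")
  if (!all(is.finite(data$value)))
    abort("replicate values must be finite")
  if ("replicate" %in% names(data)) {
    if (anyDuplicated(data[c("line", "replicate", "trait")]))
      abort("duplicated (line, replicate, trait) records")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(data, .data$line, .data$trait),
    value = mean(.data$value), support = dplyr::n(), .groups = "drop"
  )
  lines <- sort(unique(agg$line))
  traits <- sort(unique(agg$trait))
  values <- matrix(NA_real_, length(lines), length(traits),
                   dimnames = list(lines, traits))
  support <- matrix(0L, length(lines), length(traits),
                    dimnames = list(lines, traits))
  idx <- cbind(match(agg$line, lines), match(agg$trait, traits))
  values[idx] <- agg$value
  support[idx] <- agg$support
  new_trait_matrix(values, support, rep("raw", length(traits)))
}

#' Log-transform and standardize a trait matrix
#'
#' Maps each abundance column x to `ln(x + pseudo)` and then z-scores every
#' column over its non-missing entries (sample standard deviation, n - 1
#' denominator), yielding the standard scores of the log-transformed data
#' that the correlation stage consumes. Phenotypic traits measured on
#' interval scales (counts, lengths, ratios) can be z-scored without the log
#' by supplying an annotation and restricting `log_groups`.
#'
#' Columns with fewer than 3 non-missing values or zero variance after
#' transformation are dropped with a warning rather than an error, so one
#' degenerate trait cannot abort a run.
#'
#' @param m A raw `trait_matrix` from [aggregate_replicates()].
#' @param pseudo Small positive pseudo-count added before the log; every value
#'   in a logged column must exceed `-pseudo`. Spearman correlations computed
#'   downstream are invariant to this choice whenever the values are positive.
#' @param annotation Optional trait annotation (`trait`, `group`, ...). When
#'   supplied, only traits whose group is in `log_groups` are log-transformed;
#'   the rest are z-scored directly.
#' @param log_groups Annotation groups that receive the log transform.
#' @return A `trait_matrix` with transform flags `"log_standardized"` or
#'   `"standardized"`.
#' @export
log_standardize <- function(m, pseudo = 1e-9, annotation = NULL,
                            log_groups = c("primary", "secondary", "lipid",
                                           "volatile", "transcript")) {
  stopifnot(inherits(m, "trait_matrix"))
  if (!all(m$transform == "raw"))
    abort("log_standardize() expects a raw trait matrix")
  if (!is.numeric(pseudo) || pseudo < 0)
    abort("`pseudo` must be a non-negative number")
  traits <- colnames(m$values)
  do_log <- rep(TRUE, length(traits))
  if (!is.null(annotation)) {
    annotation <- as_tibble(annotation)
    grp <- annotation$group[match(traits, annotation$trait)]
    do_log <- !is.na(grp) & grp %in% log_groups
  }
  values <- m$values
  dropped <- character()
  flags <- character(length(traits))
  for (j in seq_along(traits)) {
    v <- values[, j]
    ok <- !is.na(v)
    if (do_log[j]) {
      if (any(v[ok] <= -pseudo))
        abort(sprintf("column %s has values <= -pseudo; cannot log-transform",
                      traits[j]))
      v[ok] <- log(v[ok] + pseudo)
    }
    s <- sd(v[ok])
    if (sum(ok) < 3L || !is.finite(s) || s == 0) {
      dropped <- c(dropped, traits[j])
      flags[j] <- NA_character_
      next
    }
    values[, j] <- (v - mean(v[ok])) / s
    flags[j] <- if (do_log[j]) "log_standardized" else "standardized"
  }
  if (length(dropped)) {
    warn(paste0("dropped ", length(dropped),
                " column(s) with < 3 values or zero variance: ",
                paste(dropped, collapse = ", ")))
    keep <- !(traits %in% dropped)
    values <- values[, keep, drop = FALSE]
    support <- m$support[, keep, drop = FALSE]
    flags <- flags[keep]
  } else {
    support <- m$support
  }
  new_trait_matrix(values, support, flags)
}

#' Combine standardized trait matrices from independent seasons
#'
#' For each (line, trait), takes the mean of the trait's standardized values
#' over the seasons in which it was measured; support counts are summed.
#' Averaging on the standardized scale lets seasons measured on different
#' instrument scales contribute equally. A trait present in only one season
#' passes through unchanged.
#'
#' @param per_season Non-empty list of standardized `trait_matrix` objects.
#' @return A single merged `trait_matrix` over the union of lines and traits.
#' @export
merge_seasons <- function(per_season) {
  if (!is.list(per_season) || length(per_season) == 0)
    abort("`per_season` must be a non-empty list of trait matrices")
  purrr::walk(per_season, function(m) {
    if (!inherits(m, "trait_matrix"))
      abort("all elements must be trait_matrix objects")
    if (any(m$transform == "raw"))
      abort("contract violation: merge_seasons() requires standardized matrices",
            class = "traitnet_contract_error")
  })
  flag_tbl <- purrr::map_dfr(per_season, function(m) {
    tibble(trait = colnames(m$values), flag = unname(m$transform))
  })
  conflict <- dplyr::summarise(dplyr::group_by(flag_tbl, .data$trait),
                               k = dplyr::n_distinct(.data$flag),
                               .groups = "drop")
  if (any(conflict$k > 1))
    abort(paste("contract violation: conflicting transform flags for:",
                paste(conflict$trait[conflict$k > 1], collapse = ", ")),
          class = "traitnet_contract_error")

  lines <- sort(unique(unlist(purrr::map(per_season, ~rownames(.x$values)))))
  traits <- sort(unique(flag_tbl$trait))
  sum_v <- matrix(0, length(lines), length(traits),
                  dimnames = list(lines, traits))
  cnt <- matrix(0L, length(lines), length(traits),
                dimnames = list(lines, traits))
  supp <- matrix(0L, length(lines), length(traits),
                 dimnames = list(lines, traits))
  for (m in per_season) {
    li <- match(rownames(m$values), lines)
    tj <- match(colnames(m$values), traits)
    present <- !is.na(m$values)
    v <- m$values
    v[!present] <- 0
    sum_v[li, tj] <- sum_v[li, tj] + v
    cnt[li, tj] <- cnt[li, tj] + present
    supp[li, tj] <- supp[li, tj] + m$support
  }
  values <- sum_v / cnt
  values[cnt == 0] <- NA_real_
  flags <- flag_tbl$flag[match(traits, flag_tbl$trait)]
  new_trait_matrix(values, supp, flags)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d lines x %d traits (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$transform), collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' @export
as.matrix.trait_matrix <- function(x, ...) x$values

#' Long tibble view of a trait matrix
#'
#' @param x A `trait_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `line`, `trait`, `value`, `support`,
#'   `transform` (missing cells omitted).
#' @method as_tibble trait_matrix
#' @export
as_tibble.trait_matrix <- function(x, ...) {
  long <- tibble(
    line = rep(rownames(x$values), times = ncol(x$values)),
    trait = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    support = as.vector(x$support)
  )
  long$transform <- unname(x$transform[long$trait])
  long[!is.na(long$value), ]
}

#' @rdname as_tibble.trait_matrix
#' @method tidy trait_matrix
#' @export
tidy.trait_matrix <- function(x, ...) as_tibble(x)
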