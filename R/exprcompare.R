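#' Compare a transcript's abundance between two genotype groups
#'
#' Computes the raw-scale fold change (mean of target group over mean of
#' reference group) together with a two-sided Welch t-test on log-scale
#' values, the conservative default when only significance thresholds — not
#' the test — are specified for this kind of comparison. Significance stars
#' follow the two-threshold convention: `*` for p below the first threshold
#' (default 0.05), `**` below the second (default 0.001).
#'
#' @param data Replicate table (`line`, `group`, `replicate`, `trait`,
#'   `value`) with positive values, e.g. from [generate_expression()].
#' @param transcript Trait id of the transcript to test.
#' @param ref_group,target_group Genotype group labels (values of the `group`
#'   column); each needs at least 2 replicate values.
#' @param thresholds Decreasing pair of p-value thresholds for `*` and `**`.
#' @return One-row tibble of class `group_comparison`: `transcript`,
#'   `ref_group`, `target_group`, `n_ref`, `n_target`, `fold`, `direction`
#'   (`"up"`/`"down"`/`"none"`), `statistic`, `p_value`, `stars`.
#' @export
#' @examples
#' cfg <- synth_config(n_lines = 8, seed = 3,
#'                     group_fold_changes = data.frame(
#'                       transcript = "g1", group = "PEN", fold = 20))
#' pop <- generate_population(cfg)
#' expr <- generate_expression(cfg, pop)
#' compare_groups(expr, "g1", "REF", "PEN")
compare_groups <- function(data, transcript, ref_group, target_group,
                           thresholds = c(0.05, 0.001)) {
  data <- as_tibble(data)
  need <- c("group", "trait", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(paste("replicate table lacks columns:", paste(miss, collapse = ", ")))
  d <- data[data$trait == transcript, ]
  vr <- d$value[d$group == ref_group]
  vt <- d$value[d$group == target_group]
  for (nm in c(ref_group, target_group)) {
    v <- if (nm == ref_group) vr else vt
    if (length(v) < 2L)
      abort(sprintf(
        "insufficient replication: group %s has %d value(s) for %s (need >= 2)",
        nm, length(v), transcript), class = "traitnet_replication_error")
  }
  if (any(c(vr, vt) <= 0))
    abort("expression values must be positive for log-scale testing")
  fold <- mean(vt) / mean(vr)
  lt <- log(vt); lr <- log(vr)
  if (sd(lt) == 0 && sd(lr) == 0) {
    statistic <- NA_real_
    p_value <- if (isTRUE(all.equal(mean(lt), mean(lr)))) 1 else NA_real_
  } else {
    tt <- t.test(lt, lr, var.equal = FALSE)
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
  }
  stars <- star_code(p_value, thresholds)
  out <- tibble(
    transcript = transcript, ref_group = ref_group,
    target_group = target_group, n_ref = length(vr), n_target = length(vt),
    fold = fold,
    direction = if (fold > 1) "up" else if (fold < 1) "down" else "none",
    statistic = statistic, p_value = p_value, stars = stars
  )
  structure(out, class = c("group_comparison", class(out)))
}

star_code <- function(p, thresholds = c(0.05, 0.001)) {
  if (is.na(p)) return(NA_character_)
  if (p < min(thresholds)) "**" else if (p < max(thresholds)) "*" else ""
}

#' Batch genotype-group comparisons
#'
#' Applies [compare_groups()] to each transcript and target group. Failures
#' (e.g. under-replicated groups) are collected per row in the `error`
#' column instead of aborting the batch.
#'
#' @param data Replicate table as in [compare_groups()].
#' @param transcripts Character vector of transcript ids; default all traits
#'   present in `data`.
#' @param ref_group Reference group label.
#' @param groups Character vector of target group labels.
#' @param thresholds Star thresholds, see [compare_groups()].
#' @return Tibble of class `group_comparison` with one row per attempted
#'   (transcript, target group); failed rows carry NA statistics and the
#'   error message in `error`.
#' @export
batch_compare <- function(data, transcripts = NULL, ref_group, groups,
                          thresholds = c(0.05, 0.001)) {
  data <- as_tibble(data)
  if (is.null(transcripts)) transcripts <- sort(unique(data$trait))
  if (length(transcripts) == 0 || length(groups) == 0) {
    out <- tibble(transcript = character(), ref_group = character(),
                  target_group = character(), n_ref = integer(),
                  n_target = integer(), fold = double(),
                  direction = character(), statistic = double(),
                  p_value = double(), stars = character(),
                  error = character())
    return(structure(out, class = c("group_comparison", class(out))))
  }
  grid <- tidyr::expand_grid(transcript = transcripts, target_group = groups)
  rows <- purrr::pmap(grid, function(transcript, target_group) {
    tryCatch(
      dplyr::mutate(
        compare_groups(data, transcript, ref_group, target_group, thresholds),
        error = NA_character_),
      error = function(e) tibble(
        transcript = transcript, ref_group = ref_group,
        target_group = target_group, n_ref = NA_integer_,
        n_target = NA_integer_, fold = NA_real_, direction = NA_character_,
        statistic = NA_real_, p_value = NA_real_, stars = NA_character_,
        error = conditionMessage(e))
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("group_comparison", class(out)))
}

#' Group means with standard errors, ready for bar charts
#'
#' @param data Replicate table.
#' @param transcript Transcript id.
#' @return Tibble `group`, `n`, `mean`, `se` on the raw scale.
#' @export
group_means <- function(data, transcript) {
  d <- as_tibble(data)
  d <- d[d$trait == transcript, ]
  dplyr::summarise(dplyr::group_by(d, .data$group),
                   n = dplyr::n(),
                   mean = mean(.data$value),
                   se = sd(.data$value) / sqrt(dplyr::n()),
                   .groups = "drop")
}
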