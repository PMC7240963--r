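#' Bipartite metabolite-transcript correlation network
#'
#' Correlates every metabolite (row matrix) against every transcript (column
#' matrix) across their shared genotype lines and keeps pairs with
#' `|r| >= r_cutoff` and `p < p_cutoff` — the stricter coefficient threshold
#' conventionally applied to trait/transcript networks (0.40, inclusive)
#' versus trait/trait networks (0.3, strict).
#'
#' @param metab Standardized `trait_matrix` of metabolite/lipid traits.
#' @param expr Standardized `trait_matrix` of transcript abundances on
#'   (a subset of) the same lines.
#' @param annotation Annotation covering both trait sets; transcripts should
#'   carry `group = "transcript"`.
#' @param r_cutoff Coefficient threshold, inclusive (default 0.40).
#' @param p_cutoff Significance threshold (default 0.05).
#' @param min_n,B,seed Passed to [correlate_between()].
#' @return A list with elements `network` (bipartite `trait_network`, edges
#'   run metabolite -> transcript) and `correlations` (the full
#'   `cor_result`, needed by [select_heatmap()]).
#' @export
trait_transcript_network <- function(metab, expr, annotation,
                                     r_cutoff = 0.40, p_cutoff = 0.05,
                                     min_n = 10L, B = 20000L, seed = 1L) {
  cr <- correlate_between(metab, expr, min_n = min_n, B = B, seed = seed)
  net <- build_network(cr, annotation, r_cutoff = r_cutoff,
                       p_cutoff = p_cutoff, r_rule = "geq")
  list(network = net, correlations = cr)
}

#' Select the correlation heatmap panel
#'
#' Every metabolite and every transcript with at least one network-surviving
#' correlation is represented in the heatmap; for the selected rows and
#' columns *all* pairwise coefficients are shown, including sub-threshold
#' ones, so the context of each significant link is visible.
#'
#' @param net Bipartite `trait_network` from [trait_transcript_network()].
#' @param cr The matching `cor_result`.
#' @param order `"alphabetical"` (default, deterministic) or `"hclust"`
#'   (hierarchical ordering by correlation distance `1 - r`, average
#'   linkage).
#' @return Numeric matrix of r values, rows = selected metabolites, columns =
#'   selected transcripts; empty matrix for an empty network.
#' @export
select_heatmap <- function(net, cr, order = c("alphabetical", "hclust")) {
  stopifnot(inherits(net, "trait_network"), inherits(cr, "cor_result"))
  order <- match.arg(order)
  rows <- sort(unique(net$edges$from))
  cols <- sort(unique(net$edges$to))
  m <- cr$r[rows, cols, drop = FALSE]
  if (order == "hclust" && nrow(m) > 2 && ncol(m) > 2) {
    m0 <- m
    m0[is.na(m0)] <- 0
    ro <- hclust(as.dist(1 - cor(t(m0))), method = "average")$order
    co <- hclust(as.dist(1 - cor(m0)), method = "average")$order
    m <- m[ro, co, drop = FALSE]
  }
  m
}

#' Rank candidate genes by their metabolite connectivity
#'
#' A candidate gene is any transcript with at least one edge in the bipartite
#' network. Candidates are ordered by number of links (descending), then
#' maximum coefficient magnitude (descending), then id, and annotated with
#' the dominant class among their linked traits — e.g. a lipase correlating
#' with 18 TAGs is a TAG-dominant candidate.
#'
#' @param net Bipartite `trait_network` (edges metabolite -> transcript).
#' @return Tibble with one row per candidate: `transcript`, `n_links`,
#'   `n_pos`, `n_neg`, `max_abs_r`, `dominant_class`, and a `links`
#'   list-column of per-link tibbles (`trait`, `class`, `r`, `p`, `sign`).
#' @export
rank_candidates <- function(net) {
  stopifnot(inherits(net, "trait_network"))
  if (nrow(net$edges) == 0) {
    return(tibble(transcript = character(), n_links = integer(),
                  n_pos = integer(), n_neg = integer(),
                  max_abs_r = double(), dominant_class = character(),
                  links = list()))
  }
  cls <- setNames(net$nodes$class, net$nodes$trait)
  e <- dplyr::mutate(net$edges, class = unname(cls[.data$from]))
  by_gene <- dplyr::group_by(e, transcript = .data$to)
  out <- dplyr::summarise(
    by_gene,
    n_links = dplyr::n(),
    n_pos = sum(.data$sign > 0),
    n_neg = sum(.data$sign < 0),
    max_abs_r = max(abs(.data$r)),
    dominant_class = {
      tc <- table(.data$class)  # names alphabetical; which.max takes first
      names(tc)[which.max(tc)]  # => ties resolve alphabetically
    },
    links = {
      trait <- .data$from; cls <- .data$class
      rr <- .data$r; pp <- .data$p; sg <- .data$sign
      list(tibble(trait = trait, class = cls, r = rr, p = pp, sign = sg))
    },
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$n_links), dplyr::desc(.data$max_abs_r),
                 .data$transcript)
}

#' Flat per-link candidate table for export
#'
#' @param candidates Output of [rank_candidates()].
#' @return Tibble with one row per (transcript, trait) link, candidate
#'   summary columns repeated.
#' @export
candidate_links <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(tibble(transcript = character(), n_links = integer(),
                  dominant_class = character(), trait = character(),
                  class = character(), r = double(), p = double(),
                  sign = double()))
  }
  tidyr::unnest(
    dplyr::select(candidates, "transcript", "n_links", "dominant_class",
                  "links"),
    "links"
  )
}
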