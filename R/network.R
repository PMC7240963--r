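#' Assemble a significance-filtered correlation network
#'
#' Turns a correlation result into a class-annotated network by keeping the
#' trait pairs whose coefficient magnitude clears `r_cutoff` and whose
#' permutation p-value is below `p_cutoff`. The conventional thresholds for
#' this kind of analysis are `|r| > 0.3` for trait/trait networks and
#' `|r| >= 0.4` for trait/transcript networks, both at p < 0.05; the
#' coefficient rule is strict by default (`"greater"`) and can be relaxed to
#' `"geq"` for the transcript convention.
#'
#' @param cr A `cor_result` from [correlate_all()] or [correlate_between()].
#' @param annotation Data frame `trait`, `group`, `class`, `subclass`
#'   covering every trait in `cr`; an uncovered trait is an error that lists
#'   the offenders.
#' @param r_cutoff Coefficient magnitude cut-off (default 0.3).
#' @param p_cutoff Significance cut-off (default 0.05, strict `<`).
#' @param r_rule `"greater"` (`|r| > r_cutoff`) or `"geq"`
#'   (`|r| >= r_cutoff`).
#' @param keep_isolated Keep annotated nodes with no surviving edge
#'   (default FALSE).
#' @return A `trait_network`: list with `nodes` (trait + annotation), `edges`
#'   (`from`, `to`, `r`, `p`, `n`, `sign`), and the filter provenance
#'   (`r_cutoff`, `p_cutoff`, `r_rule`, `mode`).
#' @export
build_network <- function(cr, annotation, r_cutoff = 0.3, p_cutoff = 0.05,
                          r_rule = c("greater", "geq"),
                          keep_isolated = FALSE) {
  stopifnot(inherits(cr, "cor_result"))
  r_rule <- match.arg(r_rule)
  annotation <- as_tibble(annotation)
  traits <- unique(c(rownames(cr$r), colnames(cr$r)))
  missing_ann <- setdiff(traits, annotation$trait)
  if (length(missing_ann))
    abort(paste("traits without annotation:",
                paste(sort(missing_ann), collapse = ", ")),
          class = "traitnet_annotation_error")
  if (anyDuplicated(annotation$trait))
    abort("annotation has duplicated trait ids",
          class = "traitnet_annotation_error")

  td <- tidy(cr)
  defined <- !is.na(td$r) & !is.na(td$p)
  pass_r <- if (r_rule == "greater") abs(td$r) > r_cutoff else abs(td$r) >= r_cutoff
  keep <- defined & pass_r & td$p < p_cutoff & td$trait_a != td$trait_b
  edges <- td[keep, ]
  if (cr$meta$mode == "self") {
    sp <- sort_pair(edges$trait_a, edges$trait_b)
    edges$trait_a <- sp$first
    edges$trait_b <- sp$second
    edges <- dplyr::distinct(edges, .data$trait_a, .data$trait_b,
                             .keep_all = TRUE)
  }
  edges <- dplyr::arrange(
    tibble(from = edges$trait_a, to = edges$trait_b, r = edges$r,
           p = edges$p, n = edges$n, sign = sign(edges$r)),
    .data$from, .data$to
  )
  node_ids <- if (keep_isolated) sort(traits) else
    sort(unique(c(edges$from, edges$to)))
  nodes <- annotation[match(node_ids, annotation$trait),
                      c("trait", "group", "class", "subclass")]
  structure(list(nodes = nodes, edges = edges,
                 r_cutoff = r_cutoff, p_cutoff = p_cutoff, r_rule = r_rule,
                 mode = cr$meta$mode),
            class = "trait_network")
}

#' @export
print.trait_network <- function(x, ...) {
  rule <- if (x$r_rule == "greater") ">" else ">="
  cat(sprintf("<trait_network:%s> %d nodes, %d edges (|r| %s %.2f, p < %g)\n",
              x$mode, nrow(x$nodes), nrow(x$edges), rule, x$r_cutoff,
              x$p_cutoff))
  if (nrow(x$edges))
    cat(sprintf("  positive edges: %.1f%%\n",
                100 * mean(x$edges$sign > 0)))
  invisible(x)
}

edge_classes <- function(net) {
  cls <- setNames(net$nodes$class, net$nodes$trait)
  dplyr::mutate(net$edges,
                class_a = unname(cls[.data$from]),
                class_b = unname(cls[.data$to]))
}

#' Summarize network edges by annotation-class pair
#'
#' Aggregates the edges of a network over unordered pairs of trait classes
#' (within-class pairs included), reporting for each occupied pair the edge
#' count, how many edges are positive or negative, the percentage positive,
#' and the pair's share of all network edges. Percentages are kept at full
#' precision here; [class_pair_matrix()] renders the integer-rounded
#' report-style table.
#'
#' @param net A `trait_network`.
#' @param by Node attribute to aggregate on: `"class"` (default) or
#'   `"group"`.
#' @return A tibble of class `class_pair_summary` with columns `class_a`,
#'   `class_b`, `n_edges`, `n_pos`, `n_neg`, `pct_positive`, `pct_of_edges`.
#'   Empty network gives an empty summary.
#' @export
class_pair_summary <- function(net, by = c("class", "group")) {
  stopifnot(inherits(net, "trait_network"))
  by <- match.arg(by)
  attr_map <- setNames(net$nodes[[by]], net$nodes$trait)
  e <- net$edges
  if (nrow(e) == 0) {
    out <- tibble(class_a = character(), class_b = character(),
                  n_edges = integer(), n_pos = integer(), n_neg = integer(),
                  pct_positive = double(), pct_of_edges = double())
    return(structure(out, class = c("class_pair_summary", class(out))))
  }
  ca <- unname(attr_map[e$from])
  cb <- unname(attr_map[e$to])
  sp <- sort_pair(ca, cb)
  tab <- dplyr::summarise(
    dplyr::group_by(tibble(class_a = sp$first, class_b = sp$second,
                           pos = e$sign > 0),
                    .data$class_a, .data$class_b),
    n_edges = dplyr::n(),
    n_pos = sum(.data$pos),
    n_neg = sum(!.data$pos),
    .groups = "drop"
  )
  tab$pct_positive <- 100 * tab$n_pos / tab$n_edges
  tab$pct_of_edges <- 100 * tab$n_edges / sum(tab$n_edges)
  tab <- dplyr::arrange(tab, .data$class_a, .data$class_b)
  structure(tab, class = c("class_pair_summary", class(tab)))
}

#' Report-style square table of a class-pair summary
#'
#' Renders a [class_pair_summary()] as a symmetric classes-by-classes matrix
#' of integer-rounded percent-positive values (or another statistic), the
#' layout used in published within/between-subclass correlation tables.
#'
#' @param summary A `class_pair_summary`.
#' @param value Which statistic to tabulate: `"pct_positive"` (default,
#'   rounded to integer), `"n_edges"`, or `"pct_of_edges"`.
#' @return A symmetric matrix with class names on both dimensions; pairs with
#'   no edges are NA.
#' @export
class_pair_matrix <- function(summary, value = c("pct_positive", "n_edges",
                                                 "pct_of_edges")) {
  value <- match.arg(value)
  cls <- sort(unique(c(summary$class_a, summary$class_b)))
  m <- matrix(NA_real_, length(cls), length(cls), dimnames = list(cls, cls))
  v <- summary[[value]]
  if (value == "pct_positive") v <- round(v)
  ia <- match(summary$class_a, cls)
  ib <- match(summary$class_b, cls)
  m[cbind(ia, ib)] <- v
  m[cbind(ib, ia)] <- v
  m
}

#' Whole-network summary statistics
#'
#' Node and edge counts, the overall percentage of positive edges, node
#' counts per annotation group, and each group pair's share of all edges —
#' the headline quantities quoted for correlation networks of this kind.
#'
#' @param net A `trait_network`.
#' @return A list of class `network_stats`: `n_nodes`, `n_edges`, `n_pos`,
#'   `n_neg`, `pct_positive` (NA for an empty network), `group_nodes`
#'   (tibble group/n), `group_pair_shares` (tibble group_a/group_b/n_edges/
#'   pct_of_edges).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "trait_network"))
  e <- net$edges
  n_pos <- sum(e$sign > 0)
  group_nodes <- dplyr::count(net$nodes, .data$group, name = "n")
  shares <- class_pair_summary(net, by = "group")
  structure(list(
    n_nodes = nrow(net$nodes),
    n_edges = nrow(e),
    n_pos = n_pos,
    n_neg = nrow(e) - n_pos,
    pct_positive = if (nrow(e)) 100 * n_pos / nrow(e) else NA_real_,
    group_nodes = group_nodes,
    group_pair_shares = tibble(group_a = shares$class_a,
                               group_b = shares$class_b,
                               n_edges = shares$n_edges,
                               pct_of_edges = shares$pct_of_edges)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges (%d positive, %d negative",
              x$n_nodes, x$n_edges, x$n_pos, x$n_neg))
  if (!is.na(x$pct_positive))
    cat(sprintf("; %.1f%% positive", x$pct_positive))
  cat(")\n")
  invisible(x)
}

#' Convert a trait network to an igraph graph
#'
#' Nodes carry `group`, `class`, `subclass`; edges carry `r`, `p`, `n`,
#' `sign`.
#'
#' @param net A `trait_network`.
#' @return An `igraph` object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "trait_network"))
  igraph::graph_from_data_frame(
    d = net$edges,
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Export a network to GraphML, SIF, or a round-trippable edge list
#'
#' `"edge_tsv"` writes the edge tibble as tab-separated text at full numeric
#' precision and is exactly round-trippable via [read_network_edges()].
#' `"sif"` writes one `from  pos|neg  to` interaction line per edge.
#' `"graphml"` writes GraphML (via igraph) with r/p/n/sign edge attributes
#' and the class annotation on nodes, ready for Cytoscape-style viewers.
#'
#' @param net A `trait_network`.
#' @param path Output file path.
#' @param format `"edge_tsv"`, `"sif"`, or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("edge_tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "trait_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       abort(paste("unknown export format:",
                                   paste(format, collapse = ", ")),
                             class = "traitnet_config_error"))
  if (format == "edge_tsv") {
    readr::write_tsv(net$edges, path)
  } else if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$from,
                     ifelse(net$edges$sign > 0, "pos", "neg"), net$edges$to)
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge list written by [export_network()]
#'
#' @param path Path to an edge TSV.
#' @return Edge tibble with columns `from`, `to`, `r`, `p`, `n`, `sign`.
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    from = readr::col_character(), to = readr::col_character(),
    r = readr::col_double(), p = readr::col_double(),
    n = readr::col_integer(), sign = readr::col_double()
  ))
}

#' Edge tibble of a network, annotated with endpoint classes
#'
#' @param x A `trait_network`.
#' @param ... Unused.
#' @return Tibble of edges with `class_a`/`class_b` columns appended.
#' @method tidy trait_network
#' @export
tidy.trait_network <- function(x, ...) {
  edge_classes(x)
}

#' One-row summary of a network
#'
#' @param x A `trait_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, percent positive, and the filter
#'   settings.
#' @method glance trait_network
#' @export
glance.trait_network <- function(x, ...) {
  st <- network_stats(x)
  tibble(n_nodes = st$n_nodes, n_edges = st$n_edges,
         pct_positive = st$pct_positive, r_cutoff = x$r_cutoff,
         p_cutoff = x$p_cutoff, r_rule = x$r_rule, mode = x$mode)
}
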