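#' Configuration for the synthetic introgression-line population generator
#'
#' Describes a panel of genotype lines measured for several classes of traits
#' (metabolite-like abundances and phenotype-like measurements) plus a set of
#' transcripts, with a *known planted* correlation structure: strong positive
#' blocks within trait classes, optional signed blocks between chosen class
#' pairs, chosen transcript-trait links, and multiplicative expression
#' differences between genotype groups. Everything not planted is generated
#' independently, so downstream false-positive behaviour can be measured
#' against an exact truth.
#'
#' Defaults emulate a tomato introgression-line panel: 76 lines, five trait
#' classes of ten traits each (sugars, flavonoids, TAGs, phospholipids, yield
#' phenotypes), within-class Spearman correlation 0.7, 1-12 replicates per
#' line and platform with the cultivated reference replicated most heavily,
#' and 5\% of replicate records missing.
#'
#' @param n_lines Number of genotype lines (>= 4). The first line is labelled
#'   group `REF` (cultivated reference), the last `PEN` (wild donor), the rest
#'   `IL_<k>`.
#' @param replicate_range Inclusive integer range of replicates per line and
#'   trait class; counts are drawn uniformly. The `REF` line always receives
#'   `ref_replicates` replicates (reference cultivars are typically replicated
#'   far more heavily than the panel lines).
#' @param ref_replicates Replicate count for the `REF` line.
#' @param class_spec Data frame with columns `group`, `class`, `subclass`,
#'   `n_traits`: one row per trait class. Trait ids are `<class>_<i>`.
#' @param intra_class_rho Target Spearman correlation between traits of the
#'   same class, in `[0, 1)`. `0` plants no structure.
#' @param inter_class_blocks Data frame with columns `class_a`, `class_b`,
#'   `rho`, `sign` (+1/-1): signed correlation planted between every trait of
#'   `class_a` and every trait of `class_b`.
#' @param n_transcripts Number of transcripts for [generate_expression()].
#' @param planted_links Data frame with columns `transcript`, `trait`, `rho`
#'   (signed, `|rho| < 1`): transcript-trait rank correlations to plant.
#' @param group_fold_changes Data frame with columns `transcript`, `group`,
#'   `fold` (> 0): the transcript's abundance in all lines of `group` is
#'   multiplied by `fold`.
#' @param noise_sd Residual standard deviation of replicate values on the log
#'   scale (> 0). Line-to-line (latent) variation has standard deviation 1, so
#'   the default 0.25 gives well-separated lines.
#' @param missing_rate Probability that a replicate record is dropped.
#' @param expr_replicate_range Inclusive replicate range per line for the
#'   expression platform.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return A list of class `synth_config` with the validated fields.
#' @seealso [generate_population()], [generate_expression()]
#' @export
#' @examples
#' cfg <- synth_config(n_lines = 12, class_spec = data.frame(
#'   group = "lipid", class = "TAG", subclass = "storage", n_traits = 4
#' ), seed = 7)
#' pop <- generate_population(cfg)
#' head(pop$data)
synth_config <- function(n_lines = 76,
                         replicate_range = c(1L, 12L),
                         ref_replicates = 12L,
                         class_spec = default_class_spec(),
                         intra_class_rho = 0.7,
                         inter_class_blocks = NULL,
                         n_transcripts = 10L,
                         planted_links = NULL,
                         group_fold_changes = NULL,
                         noise_sd = 0.25,
                         missing_rate = 0.05,
                         expr_replicate_range = c(3L, 6L),
                         seed = 1L) {
  cfg <- list(
    n_lines = n_lines,
    replicate_range = as.integer(replicate_range),
    ref_replicates = as.integer(ref_replicates),
    class_spec = as_tibble(class_spec),
    intra_class_rho = intra_class_rho,
    inter_class_blocks = if (is.null(inter_class_blocks)) {
      tibble(class_a = character(), class_b = character(),
             rho = double(), sign = double())
    } else as_tibble(inter_class_blocks),
    n_transcripts = as.integer(n_transcripts),
    planted_links = if (is.null(planted_links)) {
      tibble(transcript = character(), trait = character(), rho = double())
    } else as_tibble(planted_links),
    group_fold_changes = if (is.null(group_fold_changes)) {
      tibble(transcript = character(), group = character(), fold = double())
    } else as_tibble(group_fold_changes),
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    expr_replicate_range = as.integer(expr_replicate_range),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' Default five-class trait specification
#'
#' Ten traits in each of five classes spanning the trait groups of a typical
#' introgression-line study: primary metabolites (sugars), secondary
#' metabolites (flavonoids), two lipid subclasses (TAG, phospholipid) and
#' yield-related phenotypes.
#'
#' @return A tibble with columns `group`, `class`, `subclass`, `n_traits`.
#' @export
default_class_spec <- function() {
  tibble(
    group    = c("primary", "secondary", "lipid", "lipid", "phenotype"),
    class    = c("sugars", "flavonoids", "TAG", "phospholipid", "yield"),
    subclass = c("soluble sugars", "flavonols", "storage lipid",
                 "membrane lipid", "yield-related"),
    n_traits = c(10L, 10L, 10L, 10L, 10L)
  )
}

validate_synth_config <- function(cfg) {
  if (!is_count(cfg$n_lines) || cfg$n_lines < 4)
    stop_config("n_lines", "must be an integer >= 4")
  rr <- cfg$replicate_range
  if (length(rr) != 2L || any(rr < 1L) || rr[1] > rr[2])
    stop_config("replicate_range", "must be an increasing integer pair >= 1")
  er <- cfg$expr_replicate_range
  if (length(er) != 2L || any(er < 1L) || er[1] > er[2])
    stop_config("expr_replicate_range", "must be an increasing integer pair >= 1")
  cs <- cfg$class_spec
  need <- c("group", "class", "subclass", "n_traits")
  if (!all(need %in% names(cs)) || nrow(cs) == 0)
    stop_config("class_spec", "must have columns group, class, subclass, n_traits")
  if (any(cs$n_traits < 1))
    stop_config("class_spec", "needs n_traits >= 1 in every class")
  if (anyDuplicated(cs$class))
    stop_config("class_spec", "has duplicated class names")
  if (!is.numeric(cfg$intra_class_rho) || cfg$intra_class_rho < 0 ||
      cfg$intra_class_rho >= 1)
    stop_config("intra_class_rho", "must lie in [0, 1)")
  ib <- cfg$inter_class_blocks
  if (nrow(ib) > 0) {
    if (any(abs(ib$rho) >= 1) || any(ib$rho < 0))
      stop_config("inter_class_blocks", "needs rho in [0, 1) (sign goes in `sign`)")
    if (!all(ib$sign %in% c(-1, 1)))
      stop_config("inter_class_blocks", "needs sign in {-1, +1}")
    missing_cls <- setdiff(unique(c(ib$class_a, ib$class_b)), cs$class)
    if (length(missing_cls))
      stop_config("inter_class_blocks",
                  paste("references unknown classes:",
                        paste(missing_cls, collapse = ", ")))
  }
  traits <- trait_ids(cs)
  pl <- cfg$planted_links
  if (nrow(pl) > 0) {
    if (any(abs(pl$rho) >= 1))
      stop_config("planted_links", "needs |rho| < 1")
    unknown <- setdiff(pl$trait, traits)
    if (length(unknown))
      stop_config("planted_links",
                  paste("references unknown traits:",
                        paste(unknown, collapse = ", ")))
  }
  gf <- cfg$group_fold_changes
  if (nrow(gf) > 0 && any(gf$fold <= 0))
    stop_config("group_fold_changes", "needs fold > 0")
  gene_ids <- paste0("g", seq_len(cfg$n_transcripts))
  bad_g <- setdiff(c(pl$transcript, gf$transcript), gene_ids)
  if (length(bad_g))
    stop_config("n_transcripts",
                paste("too small for referenced transcripts:",
                      paste(bad_g, collapse = ", ")))
  clash <- intersect(gf$transcript, pl$transcript)
  if (length(clash))
    stop_config("group_fold_changes",
                paste("transcripts cannot also carry planted_links:",
                      paste(clash, collapse = ", ")))
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop_config("noise_sd", "must be > 0")
  if (!is.numeric(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_config("missing_rate", "must lie in [0, 1)")
  if (!is_count(cfg$seed)) stop_config("seed", "must be an integer")
  invisible(cfg)
}

trait_ids <- function(class_spec) {
  unlist(purrr::pmap(class_spec, function(group, class, subclass, n_traits) {
    paste0(class, "_", seq_len(n_traits))
  }), use.names = FALSE)
}

line_ids <- function(n_lines) {
  c("M82", sprintf("IL_%02d", seq_len(n_lines - 2L)), "PEN")
}

line_groups <- function(n_lines) {
  c("REF", paste0("IL_", seq_len(n_lines - 2L)), "PEN")
}

# Spearman -> Pearson conversion for a bivariate Gaussian copula:
# rho_S = (6/pi) asin(rho_P / 2)  =>  rho_P = 2 sin(pi rho_S / 6).
# Planting rho_P on the latent scale therefore yields the target Spearman
# after any monotone transform of the margins.
copula_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Latent correlation matrix over all traits: equicorrelated within-class
# blocks plus signed inter-class blocks, zero elsewhere. A small ridge is
# added if the composed matrix is not positive definite.
latent_sigma <- function(cfg) {
  cs <- cfg$class_spec
  traits <- trait_ids(cs)
  cls <- rep(cs$class, cs$n_traits)
  p <- length(traits)
  sigma <- diag(p)
  rho_p <- copula_pearson(cfg$intra_class_rho)
  for (k in cs$class) {
    idx <- which(cls == k)
    sigma[idx, idx] <- rho_p
  }
  ib <- cfg$inter_class_blocks
  for (b in seq_len(nrow(ib))) {
    ia <- which(cls == ib$class_a[b])
    jb <- which(cls == ib$class_b[b])
    r <- copula_pearson(ib$rho[b]) * ib$sign[b]
    sigma[ia, jb] <- r
    sigma[jb, ia] <- r
  }
  diag(sigma) <- 1
  ridge <- 0
  repeat {
    ch <- tryCatch(chol(sigma + ridge * diag(p)), error = function(e) NULL)
    if (!is.null(ch)) break
    ridge <- if (ridge == 0) 1e-8 else ridge * 10
    if (ridge > 0.1)
      abort("latent correlation matrix cannot be made positive definite; weaken the planted blocks")
  }
  dimnames(sigma) <- list(traits, traits)
  list(sigma = sigma, chol = ch, traits = traits, cls = cls)
}

#' Generate a synthetic introgression-line trait dataset with known structure
#'
#' Draws line-level latent trait values from a Gaussian copula whose
#' correlation blocks realise the planted structure of the configuration, then
#' emits replicate-level observations on a positive abundance scale
#' (log-normal around each line's latent mean) with heterogeneous replicate
#' counts and missing records. Because Spearman correlation is invariant to
#' the exponential map, downstream rank correlations of the line means recover
#' the planted values (attenuated slightly by replicate noise).
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_population` with elements
#'   \describe{
#'     \item{data}{Replicate table: tibble with columns `line`, `group`,
#'       `replicate`, `trait`, `value` (positive).}
#'     \item{annotation}{Tibble `trait`, `group`, `class`, `subclass` covering
#'       every generated trait.}
#'     \item{truth}{`synthetic_truth`: `planted_edges` (trait_a, trait_b,
#'       sign, rho), `null_pairs` (independent pairs), `planted_gene_links`,
#'       `group_effects`.}
#'   }
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  lat <- latent_sigma(config)
  n <- config$n_lines
  lines <- line_ids(n)
  groups <- line_groups(n)
  cs <- config$class_spec

  with_seed(config$seed, {
    z <- matrix(rnorm(n * length(lat$traits)), nrow = n) %*% lat$chol
    dimnames(z) <- list(lines, lat$traits)
    mu <- runif(length(lat$traits), min = 2, max = 8)

    # replicate counts per (line, class): uniform in replicate_range,
    # reference line pinned at ref_replicates
    rec <- purrr::map_dfr(seq_len(nrow(cs)), function(ci) {
      k_class <- cs$class[ci]
      tr <- lat$traits[lat$cls == k_class]
      nrep <- sample_int_range(config$replicate_range, n)
      nrep[1] <- config$ref_replicates
      purrr::map_dfr(seq_len(n), function(li) {
        reps <- seq_len(nrep[li])
        tidyr::expand_grid(line = lines[li], replicate = reps, trait = tr)
      })
    })
    latent <- mu[match(rec$trait, lat$traits)] +
      z[cbind(match(rec$line, lines), match(rec$trait, lat$traits))]
    rec$value <- exp(latent + rnorm(nrow(rec), sd = config$noise_sd))
    if (config$missing_rate > 0) {
      keep <- runif(nrow(rec)) >= config$missing_rate
      rec <- rec[keep, , drop = FALSE]
    }
    rec$group <- groups[match(rec$line, lines)]
    data <- dplyr::arrange(
      dplyr::select(as_tibble(rec), "line", "group", "replicate", "trait", "value"),
      .data$line, .data$trait, .data$replicate
    )

    annotation <- tibble(
      trait = lat$traits,
      group = rep(cs$group, cs$n_traits),
      class = rep(cs$class, cs$n_traits),
      subclass = rep(cs$subclass, cs$n_traits)
    )

    truth <- build_truth(config, lat)
    structure(list(data = data, annotation = annotation, truth = truth),
              class = "synth_population")
  })
}

build_truth <- function(cfg, lat) {
  traits <- lat$traits
  cls <- lat$cls
  pairs <- t(utils::combn(traits, 2L))
  # canonical unordered-pair orientation (alphabetical), matching the
  # orientation of network edges so truth and edges join by key
  swap <- pairs[, 1] > pairs[, 2]
  pairs[swap, ] <- pairs[swap, c(2, 1)]
  pair_cls_a <- cls[match(pairs[, 1], traits)]
  pair_cls_b <- cls[match(pairs[, 2], traits)]

  planted <- tibble(trait_a = character(), trait_b = character(),
                    sign = double(), rho = double())
  if (cfg$intra_class_rho > 0) {
    same <- pair_cls_a == pair_cls_b
    planted <- tibble(trait_a = pairs[same, 1], trait_b = pairs[same, 2],
                      sign = 1, rho = cfg$intra_class_rho)
  }
  ib <- cfg$inter_class_blocks
  for (b in seq_len(nrow(ib))) {
    hit <- (pair_cls_a == ib$class_a[b] & pair_cls_b == ib$class_b[b]) |
      (pair_cls_a == ib$class_b[b] & pair_cls_b == ib$class_a[b])
    planted <- dplyr::bind_rows(planted, tibble(
      trait_a = pairs[hit, 1], trait_b = pairs[hit, 2],
      sign = ib$sign[b], rho = ib$rho[b]
    ))
  }
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  planted_key <- paste(planted$trait_a, planted$trait_b, sep = "\r")
  nulls <- !(key %in% planted_key)
  truth <- list(
    planted_edges = planted,
    null_pairs = tibble(trait_a = pairs[nulls, 1], trait_b = pairs[nulls, 2]),
    planted_gene_links = dplyr::mutate(cfg$planted_links,
                                       sign = sign(.data$rho)),
    group_effects = cfg$group_fold_changes
  )
  structure(truth, class = "synthetic_truth")
}

#' Generate transcript abundances tied to a synthetic population
#'
#' Produces a replicate-level expression table on the same genotype lines as
#' an existing synthetic population. Each transcript named in the
#' configuration's `planted_links` is generated to have the requested rank
#' correlation with its target trait (via a Gaussian copula on the trait's
#' standardized line-mean log abundance); all other transcripts are
#' independent of everything. `group_fold_changes` are applied
#' multiplicatively to all lines of the named genotype group, emulating
#' allele-dependent expression differences between the cultivated reference,
#' introgression lines, and the wild donor.
#'
#' @param config The [synth_config()] used for the population.
#' @param population The `synth_population` returned by
#'   [generate_population()] (its trait data anchor the planted links).
#' @param lines Optional character vector restricting the expression platform
#'   to a subset of lines (e.g. the lines actually assayed by RNA-seq).
#' @return A replicate table tibble (`line`, `group`, `replicate`, `trait`,
#'   `value`) whose `trait` column holds transcript ids `g1`, `g2`, ...
#' @export
generate_expression <- function(config, population, lines = NULL) {
  stopifnot(inherits(config, "synth_config"),
            inherits(population, "synth_population"))
  pl <- config$planted_links
  have <- unique(population$data$trait)
  unknown <- setdiff(pl$trait, have)
  if (length(unknown))
    stop_config("planted_links",
                paste("references traits absent from the population:",
                      paste(unknown, collapse = ", ")))

  all_lines <- unique(population$data$line)
  if (is.null(lines)) lines <- all_lines
  if (!all(lines %in% all_lines))
    abort("`lines` must be a subset of the population's lines")
  groups <- population$data$group[match(lines, population$data$line)]
  n <- length(lines)
  gene_ids <- paste0("g", seq_len(config$n_transcripts))
  bad_gene <- setdiff(pl$transcript, gene_ids)
  if (length(bad_gene))
    stop_config("planted_links",
                paste("references transcripts beyond n_transcripts:",
                      paste(bad_gene, collapse = ", ")))

  # standardized line-mean log abundance of each linked trait: the observable
  # monotone image of the trait's latent line value
  trait_scores <- function(trait) {
    d <- population$data[population$data$trait == trait, ]
    m <- tapply(log(d$value), d$line, mean)
    s <- (m - mean(m, na.rm = TRUE)) / sd(m, na.rm = TRUE)
    out <- s[match(lines, names(m))]
    out[is.na(out)] <- 0
    out
  }

  with_seed(config$seed + 500009L, {
    lat <- matrix(rnorm(n * length(gene_ids)), nrow = n,
                  dimnames = list(lines, gene_ids))
    for (g in unique(pl$transcript)) {
      links <- pl[pl$transcript == g, ]
      s <- purrr::map(links$trait, trait_scores)
      w <- copula_pearson(abs(links$rho)) * sign(links$rho)
      tot <- sum(w^2)
      if (tot >= 1)
        stop_config("planted_links",
                    sprintf("combined planted correlation for %s is too strong", g))
      lat[, g] <- Reduce(`+`, purrr::map2(s, w, `*`)) +
        sqrt(1 - tot) * lat[, g]
    }
    mu <- runif(length(gene_ids), min = 2, max = 8)
    gf <- config$group_fold_changes
    # allele-driven transcripts: the genotype-group offset IS their genetic
    # signal, so they carry no independent line-level latent variation --
    # only the planted fold plus replicate noise (cis-regulation scenario)
    lat[, unique(gf$transcript)] <- 0
    nrep <- sample_int_range(config$expr_replicate_range, n)
    nrep[groups == "REF"] <- config$ref_replicates
    rec <- purrr::map_dfr(seq_len(n), function(li) {
      tidyr::expand_grid(line = lines[li], replicate = seq_len(nrep[li]),
                         trait = gene_ids)
    })
    latent <- mu[match(rec$trait, gene_ids)] +
      lat[cbind(match(rec$line, lines), match(rec$trait, gene_ids))]
    for (b in seq_len(nrow(gf))) {
      hit <- rec$trait == gf$transcript[b] &
        groups[match(rec$line, lines)] == gf$group[b]
      latent[hit] <- latent[hit] + log(gf$fold[b])
    }
    rec$value <- exp(latent + rnorm(nrow(rec), sd = config$noise_sd))
    rec$group <- groups[match(rec$line, lines)]
    dplyr::arrange(
      dplyr::select(as_tibble(rec), "line", "group", "replicate", "trait", "value"),
      .data$line, .data$trait, .data$replicate
    )
  })
}

#' @export
print.synth_population <- function(x, ...) {
  cat(sprintf(
    "<synth_population> %d lines, %d traits, %d replicate records\n",
    dplyr::n_distinct(x$data$line), nrow(x$annotation), nrow(x$data)))
  cat(sprintf("  planted edges: %d, null pairs: %d\n",
              nrow(x$truth$planted_edges), nrow(x$truth$null_pairs)))
  invisible(x)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d lines, %d traits in %d classes, intra-class rho %.2f, seed %d\n",
    x$n_lines, sum(x$class_spec$n_traits), nrow(x$class_spec),
    x$intra_class_rho, x$seed))
  invisible(x)
}
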