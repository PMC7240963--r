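#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), computed on
#' the pairwise-complete observations. This is the elementary statistic behind
#' every edge of the correlation networks; being rank-based it is invariant to
#' strictly monotone transforms of either variable, so it does not matter
#' whether it is fed raw abundances, log abundances, or standard scores.
#'
#' @param x,y Numeric vectors of equal length; entries where either is
#'   missing are dropped pairwise.
#' @return The coefficient in `[-1, 1]`, or `NA` when fewer than 3 complete
#'   pairs remain or either rank vector has zero variance (the undefined-result
#'   marker).
#' @export
#' @examples
#' spearman_rho(1:4, c(10, 20, 30, 40))   # 1
#' spearman_rho(1:4, 4:1)                 # -1
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  rank_rho(rank(x[ok]), rank(y[ok]))
}

# rho from precomputed rank vectors; NA when a margin is constant
rank_rho <- function(rx, ry) {
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  den <- sqrt(sum(rxc^2) * sum(ryc^2))
  if (den == 0) return(NA_real_)
  sum(rxc * ryc) / den
}

# All n! permutations of 1:n as an (n! x n) matrix, in lexicographic-ish
# recursive order. Used only for exhaustive enumeration at small n.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# shared tolerance when comparing permutation |rho| against the observed
# value: rho values are ratios of integers over a common denominator, so a
# tiny epsilon only absorbs floating-point noise, never a real difference
RHO_EPS <- 1e-12

#' Permutation p-value for a Spearman correlation
#'
#' Two-sided permutation test of no association: the pairing of `y` against
#' `x` is broken uniformly at random (Monte-Carlo mode) or by complete
#' enumeration of all `n!` permutations (exhaustive mode), and the p-value is
#' the probability of a permuted `|rho|` at least as large as the observed
#' one. Monte-Carlo uses the add-one estimator `(1 + hits) / (B + 1)`, which
#' is never zero and counts the observed pairing as one of the draws;
#' exhaustive enumeration includes the identity permutation by construction,
#' so both modes return p-values in `(0, 1]`.
#'
#' @param x,y Numeric vectors; missing entries dropped pairwise.
#' @param B Number of Monte-Carlo permutations (default 20000, at least 100).
#' @param mode `"monte_carlo"` or `"exhaustive"`. Exhaustive mode refuses
#'   factorials above `exhaustive_ceiling`.
#' @param seed Optional integer seed for the Monte-Carlo stream (the caller's
#'   RNG state is left untouched). `NULL` uses the current RNG state.
#' @param exhaustive_ceiling Largest `n!` the exhaustive mode will enumerate
#'   (default `40320 = 8!`).
#' @return The p-value in `(0, 1]`, or `NA` when the coefficient itself is
#'   undefined.
#' @export
#' @examples
#' perm_pvalue(1:5, 2 * (1:5), mode = "exhaustive")   # 2/120
perm_pvalue <- function(x, y, B = 20000L,
                        mode = c("monte_carlo", "exhaustive"),
                        seed = NULL, exhaustive_ceiling = 40320L) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  r_obs <- rank_rho(rx, ry)
  if (is.na(r_obs)) return(NA_real_)
  if (mode == "exhaustive") {
    if (factorial(length(x)) > exhaustive_ceiling)
      abort(sprintf("exhaustive mode needs n! <= %d (n = %d)",
                    exhaustive_ceiling, length(x)),
            class = "traitnet_config_error")
    return(perm_p_exhaustive(rx, ry, r_obs))
  }
  if (!is_count(B) || B < 100)
    abort("monte_carlo mode needs B >= 100 permutations",
          class = "traitnet_config_error")
  if (is.null(seed)) {
    perm_p_mc(rx, ry, r_obs, as.integer(B))
  } else {
    with_seed(seed, perm_p_mc(rx, ry, r_obs, as.integer(B)))
  }
}

perm_p_exhaustive <- function(rx, ry, r_obs) {
  P <- all_permutations(length(ry))
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  den <- sqrt(sum(rxc^2) * sum(ryc^2))
  # each row of P is one reordering of y's ranks; sum(rxc) = 0 makes
  # re-centering unnecessary
  r_all <- as.vector(matrix(ryc[P], nrow(P), ncol(P)) %*% rxc) / den
  mean(abs(r_all) >= abs(r_obs) - RHO_EPS)
}

perm_p_mc <- function(rx, ry, r_obs, B, block = 20000L) {
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  den <- sqrt(sum(rxc^2) * sum(ryc^2))
  n <- length(ry)
  hits <- 0L
  done <- 0L
  while (done < B) {
    b <- min(block, B - done)
    P <- vapply(seq_len(b), function(k) ryc[sample.int(n)], numeric(n))
    r_b <- as.vector(crossprod(rxc, P)) / den
    hits <- hits + sum(abs(r_b) >= abs(r_obs) - RHO_EPS)
    done <- done + b
  }
  (1 + hits) / (B + 1)
}

new_cor_result <- function(r, p, n, mode, B, seed, min_n, p_adjust = "none") {
  structure(list(r = r, p = p, n = n,
                 meta = list(mode = mode, B = B, seed = seed, min_n = min_n,
                             p_adjust = p_adjust)),
            class = "cor_result")
}

values_matrix <- function(m) {
  if (inherits(m, "trait_matrix")) return(m$values)
  if (is.matrix(m)) {
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
    if (is.null(rownames(m))) rownames(m) <- paste0("L", seq_len(nrow(m)))
    return(m)
  }
  if (is.data.frame(m)) {
    d <- as.data.frame(m)
    if ("line" %in% names(d)) {
      rn <- d$line
      d <- d[setdiff(names(d), c("line", "group"))]
    } else rn <- paste0("L", seq_len(nrow(d)))
    v <- as.matrix(d)
    rownames(v) <- rn
    return(v)
  }
  abort("expected a trait_matrix, matrix, or data frame")
}

#' All-against-all Spearman correlations with permutation p-values
#'
#' Computes the full symmetric Spearman matrix over the columns of a trait
#' matrix together with a permutation p-value and pairwise-complete sample
#' size for every unordered pair. Pairs with fewer than `min_n` complete
#' observations are left undefined (NA) rather than raising an error. The
#' permutation stream of each pair is seeded deterministically from
#' `(seed, i, j)`, so results are reproducible regardless of evaluation
#' order.
#'
#' @param m `trait_matrix`, numeric matrix (lines in rows), or wide data
#'   frame with a `line` column.
#' @param min_n Minimum pairwise-complete sample size (default 10).
#' @param B Monte-Carlo permutations per pair (default 20000).
#' @param seed Master seed for the per-pair permutation streams.
#' @param p_adjust `"none"` (default; edges are filtered on raw permutation
#'   p-values) or `"BH"` for Benjamini-Hochberg adjustment across all defined
#'   pairs.
#' @return A `cor_result`: list with matrices `r`, `p`, `n` and a `meta`
#'   record (mode, B, seed, min_n, p_adjust). Use [tidy()] for a long
#'   pair-per-row view.
#' @export
correlate_all <- function(m, min_n = 10L, B = 20000L, seed = 1L,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  X <- values_matrix(m)
  traits <- colnames(X)
  k <- length(traits)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  nm <- matrix(0L, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  obs <- is.finite(X)
  for (i in seq_len(k)) {
    nm[i, i] <- sum(obs[, i])
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- obs[, i] & obs[, j]
      nij <- sum(ok)
      nm[i, j] <- nm[j, i] <- nij
      if (nij < min_n) next
      rx <- rank(X[ok, i]); ry <- rank(X[ok, j])
      rho <- rank_rho(rx, ry)
      if (is.na(rho)) next
      r[i, j] <- r[j, i] <- rho
      pij <- with_seed(pair_seed(seed, i, j),
                       perm_p_mc(rx, ry, rho, as.integer(B)))
      p[i, j] <- p[j, i] <- pij
    }
  }
  res <- new_cor_result(r, p, nm, "self", B, seed, min_n, p_adjust)
  if (p_adjust == "BH") res <- adjust_cor_result(res)
  res
}

#' Spearman correlations between the columns of two matrices
#'
#' Rectangular analogue of [correlate_all()] for two trait matrices sharing
#' genotype lines, e.g. metabolite levels against transcript abundances
#' measured on the same introgression lines. Lines are matched by row name;
#' the correlation of each (row-trait, column-trait) pair is computed on the
#' pairwise-complete shared lines.
#'
#' @inheritParams correlate_all
#' @param a,b `trait_matrix` objects (or matrices/data frames); rows of the
#'   result are `a`'s traits, columns are `b`'s traits.
#' @return A `cor_result` with `meta$mode == "between"`.
#' @export
correlate_between <- function(a, b, min_n = 10L, B = 20000L, seed = 1L,
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  A <- values_matrix(a)
  Bm <- values_matrix(b)
  shared <- intersect(rownames(A), rownames(Bm))
  if (length(shared) == 0)
    abort("no shared lines between the two matrices",
          class = "traitnet_alignment_error")
  if (length(shared) < min_n)
    abort(sprintf("only %d shared lines; min_n is %d", length(shared), min_n),
          class = "traitnet_alignment_error")
  A <- A[shared, , drop = FALSE]
  Bm <- Bm[shared, , drop = FALSE]
  ta <- colnames(A); tb <- colnames(Bm)
  r <- matrix(NA_real_, length(ta), length(tb), dimnames = list(ta, tb))
  p <- r
  nm <- matrix(0L, length(ta), length(tb), dimnames = list(ta, tb))
  oa <- is.finite(A); ob <- is.finite(Bm)
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      ok <- oa[, i] & ob[, j]
      nij <- sum(ok)
      nm[i, j] <- nij
      if (nij < min_n) next
      rx <- rank(A[ok, i]); ry <- rank(Bm[ok, j])
      rho <- rank_rho(rx, ry)
      if (is.na(rho)) next
      r[i, j] <- rho
      p[i, j] <- with_seed(pair_seed(seed, i, j),
                           perm_p_mc(rx, ry, rho, as.integer(B)))
    }
  }
  res <- new_cor_result(r, p, nm, "between", B, seed, min_n, p_adjust)
  if (p_adjust == "BH") res <- adjust_cor_result(res)
  res
}

adjust_cor_result <- function(res) {
  if (res$meta$mode == "self") {
    iu <- upper.tri(res$p)
    res$p[iu] <- p.adjust(res$p[iu], method = "BH")
    res$p[lower.tri(res$p)] <- t(res$p)[lower.tri(res$p)]
  } else {
    res$p[] <- p.adjust(res$p, method = "BH")
  }
  res
}

#' @export
print.cor_result <- function(x, ...) {
  defined <- sum(!is.na(x$p)) / (if (x$meta$mode == "self") 2 else 1)
  cat(sprintf("<cor_result:%s> %d x %d traits, %d defined pairs, B = %d, min_n = %d\n",
              x$meta$mode, nrow(x$r), ncol(x$r), defined, x$meta$B,
              x$meta$min_n))
  invisible(x)
}

#' Long pair-per-row view of a correlation result
#'
#' @param x A `cor_result`.
#' @param ... Unused.
#' @return Tibble with `trait_a`, `trait_b`, `r`, `p`, `n`; one row per
#'   unordered pair (self mode) or per cell (between mode). Undefined pairs
#'   carry NA coefficients.
#' @method tidy cor_result
#' @export
tidy.cor_result <- function(x, ...) {
  if (x$meta$mode == "self") {
    idx <- which(upper.tri(x$r), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(nrow(x$r)),
                                 col = seq_len(ncol(x$r))))
  }
  tibble(
    trait_a = rownames(x$r)[idx[, 1]],
    trait_b = colnames(x$r)[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    n = x$n[idx]
  )
}

#' One-row summary of a correlation result
#'
#' @param x A `cor_result`.
#' @param ... Unused.
#' @return Tibble with pair counts and metadata.
#' @method glance cor_result
#' @export
glance.cor_result <- function(x, ...) {
  td <- tidy(x)
  tibble(
    mode = x$meta$mode,
    n_pairs = nrow(td),
    n_defined = sum(!is.na(td$r)),
    B = x$meta$B,
    min_n = x$meta$min_n,
    p_adjust = x$meta$p_adjust,
    seed = x$meta$seed
  )
}
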