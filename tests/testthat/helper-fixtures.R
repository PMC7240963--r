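# Shared fixtures, built in code. Small configurations keep the unit suite
# fast; the acceptance tests use the full-size study conditions.

two_class_spec <- function(n_traits = c(4L, 4L)) {
  data.frame(
    group = c("lipid", "lipid"),
    class = c("TAG", "phospholipid"),
    subclass = c("storage", "membrane"),
    n_traits = n_traits
  )
}

small_config <- function(seed = 1, ...) {
  synth_config(n_lines = 16, class_spec = two_class_spec(),
               replicate_range = c(2L, 4L), ref_replicates = 4L,
               missing_rate = 0, seed = seed, ...)
}

# independent-trait panel with five planted transcript-trait links,
# one of them negative (the trait/transcript fixture)
bipartite_links <- function() {
  data.frame(
    transcript = paste0("g", 1:5),
    trait = c("TAG_1", "TAG_2", "TAG_3", "phospholipid_1", "phospholipid_2"),
    rho = c(0.6, 0.6, 0.6, 0.6, -0.6)
  )
}

bipartite_config <- function(seed = 21) {
  synth_config(
    n_lines = 76, intra_class_rho = 0,
    class_spec = two_class_spec(c(6L, 6L)),
    n_transcripts = 10L, planted_links = bipartite_links(),
    seed = seed
  )
}

transcript_annotation <- function(n = 10) {
  data.frame(trait = paste0("g", seq_len(n)), group = "transcript",
             class = "lipid-related gene", subclass = "transcript")
}

# standardized matrices + annotation for a population and optional expression
standardize_population <- function(pop) {
  suppressWarnings(
    log_standardize(aggregate_replicates(pop$data), annotation = pop$annotation)
  )
}

# hand-built cor_result, for exercising the network stage without the
# correlation machinery
manual_cor_result <- function(pairs) {
  traits <- sort(unique(c(pairs$trait_a, pairs$trait_b)))
  k <- length(traits)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  p <- r
  n <- matrix(0L, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$trait_a[i]; b <- pairs$trait_b[i]
    r[a, b] <- r[b, a] <- pairs$r[i]
    p[a, b] <- p[b, a] <- pairs$p[i]
    n[a, b] <- n[b, a] <- 76L
  }
  traitnet:::new_cor_result(r, p, n, "self", 0L, 0L, 10L)
}

uniform_annotation <- function(traits, group = "lipid", class = "TAG",
                               subclass = "storage") {
  data.frame(trait = traits, group = group, class = class,
             subclass = subclass)
}
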