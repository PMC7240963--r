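test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synth_config(n_lines = 3), "n_lines")
  expect_error(synth_config(intra_class_rho = 1), "intra_class_rho")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  expect_error(
    synth_config(class_spec = data.frame(group = "lipid", class = "TAG",
                                         subclass = "s", n_traits = 0L)),
    "class_spec")
  expect_error(
    synth_config(planted_links = data.frame(transcript = "g1",
                                            trait = "nonexistent", rho = 0.5)),
    "planted_links")
  expect_error(
    synth_config(inter_class_blocks = data.frame(class_a = "TAG",
                                                 class_b = "unknown",
                                                 rho = 0.5, sign = 1)),
    "inter_class_blocks")
  expect_error(
    synth_config(n_transcripts = 2,
                 group_fold_changes = data.frame(transcript = "g9",
                                                 group = "PEN", fold = 2)),
    "n_transcripts")
  expect_error(
    synth_config(planted_links = data.frame(transcript = "g1", trait = "TAG_1",
                                            rho = 0.5),
                 group_fold_changes = data.frame(transcript = "g1",
                                                 group = "PEN", fold = 2)),
    "group_fold_changes")
})

test_that("generation is deterministic given config and seed", {
  cfg <- small_config(seed = 7)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$data, p2$data)
  expect_identical(p1$annotation, p2$annotation)
  expect_identical(p1$truth$planted_edges, p2$truth$planted_edges)
  e1 <- generate_expression(cfg, p1)
  e2 <- generate_expression(cfg, p2)
  expect_identical(e1, e2)
  p3 <- generate_population(small_config(seed = 8))
  expect_false(identical(p1$data, p3$data))
})

test_that("truth partitions trait pairs: planted and null pairs are disjoint and exhaustive", {
  cfg <- small_config(seed = 3)
  pop <- generate_population(cfg)
  tr <- pop$truth
  pk <- paste(tr$planted_edges$trait_a, tr$planted_edges$trait_b)
  nk <- paste(tr$null_pairs$trait_a, tr$null_pairs$trait_b)
  expect_length(intersect(pk, nk), 0)
  expect_equal(length(pk) + length(nk), choose(nrow(pop$annotation), 2))
  # every planted edge references generated traits
  expect_true(all(c(tr$planted_edges$trait_a, tr$planted_edges$trait_b) %in%
                    pop$annotation$trait))
  # annotation covers every trait in the data
  expect_setequal(unique(pop$data$trait), pop$annotation$trait)
})

test_that("zero intra-class correlation plants nothing", {
  cfg <- small_config(seed = 5, intra_class_rho = 0)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$truth$planted_edges), 0)
  expect_equal(nrow(pop$truth$null_pairs), choose(8, 2))
})

test_that("replicate structure honours the configured ranges and reference replication", {
  cfg <- small_config(seed = 2)
  pop <- generate_population(cfg)
  counts <- dplyr::count(pop$data, line, trait)
  expect_true(all(counts$n >= 1 & counts$n <= 4))
  ref <- counts[counts$line == "M82", ]
  expect_true(all(ref$n == 4))
  expect_true(all(pop$data$value > 0))
  expect_setequal(unique(pop$data$group),
                  c("REF", paste0("IL_", 1:14), "PEN"))
})

test_that("two-trait fixture with near-unit target reproduces the frozen empirical rho", {
  cfg <- synth_config(n_lines = 76, intra_class_rho = 0.99,
                      class_spec = data.frame(group = "lipid", class = "TAG",
                                              subclass = "storage",
                                              n_traits = 2L),
                      seed = 42)
  pop <- generate_population(cfg)
  m <- aggregate_replicates(pop$data)
  r <- spearman_rho(m$values[, "TAG_1"], m$values[, "TAG_2"])
  expect_equal(r, 0.981517, tolerance = 1e-5)      # frozen regression value
  expect_lt(abs(r - 0.99), 0.05)                   # calibration band
})

test_that("planted and null correlations are calibrated over repeated draws", {
  seeds <- 1:20
  stats <- purrr::map_dfr(seeds, function(s) {
    cfg <- synth_config(n_lines = 76, class_spec = two_class_spec(),
                        seed = s)
    pop <- generate_population(cfg)
    X <- aggregate_replicates(pop$data)$values
    tr <- pop$truth
    planted <- mean(mapply(function(a, b) spearman_rho(X[, a], X[, b]),
                           tr$planted_edges$trait_a, tr$planted_edges$trait_b))
    null <- mean(mapply(function(a, b) spearman_rho(X[, a], X[, b]),
                        tr$null_pairs$trait_a, tr$null_pairs$trait_b))
    tibble::tibble(planted = planted, null = null)
  })
  expect_lt(abs(mean(stats$planted) - 0.7), 0.1)
  expect_lt(abs(mean(stats$null)), 0.05)
})

test_that("planted transcript links carry the requested sign; unlinked transcripts are null", {
  cfg <- bipartite_config(seed = 11)
  pop <- generate_population(cfg)
  expr <- generate_expression(cfg, pop)
  zm <- aggregate_replicates(pop$data)$values
  ze <- aggregate_replicates(expr)$values
  links <- bipartite_links()
  for (i in seq_len(nrow(links))) {
    r <- spearman_rho(zm[rownames(ze), links$trait[i]], ze[, links$transcript[i]])
    expect_equal(sign(r), sign(links$rho[i]))
    expect_gt(abs(r), 0.3)
  }
  # transcripts without planted links: independent by construction
  null_r <- sapply(paste0("g", 6:10), function(g)
    spearman_rho(zm[rownames(ze), "TAG_4"], ze[, g]))
  expect_true(all(abs(null_r) < 0.35))
})

test_that("planted group fold changes are realised on the raw mean scale", {
  cfg <- synth_config(n_lines = 10, seed = 4,
                      group_fold_changes = data.frame(transcript = "g6",
                                                      group = "PEN",
                                                      fold = 20))
  pop <- generate_population(cfg)
  expr <- generate_expression(cfg, pop)
  g6 <- expr[expr$trait == "g6", ]
  fold <- mean(g6$value[g6$group == "PEN"]) / mean(g6$value[g6$group == "REF"])
  expect_lt(abs(fold - 20) / 20, 0.3)
})

test_that("expression generation validates its inputs", {
  cfg <- small_config(seed = 1)
  pop <- generate_population(cfg)
  expect_error(generate_expression(cfg, pop, lines = "not_a_line"), "subset")
  cfg_bad <- cfg
  cfg_bad$planted_links <- tibble::tibble(transcript = "g1",
                                          trait = "missing_trait", rho = 0.5)
  expect_error(generate_expression(cfg_bad, pop), "absent")
})
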