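test_that("edge filters are strict on both coefficient and significance", {
  pairs <- tibble::tibble(
    trait_a = c("a", "a", "b", "c"),
    trait_b = c("b", "c", "c", "d"),
    r = c(0.5, -0.4, 0.2, 0.5),
    p = c(0.01, 0.01, 0.01, 0.6)
  )
  cr <- manual_cor_result(pairs)
  ann <- uniform_annotation(c("a", "b", "c", "d"))
  net <- build_network(cr, ann, r_cutoff = 0.3, p_cutoff = 0.05)
  expect_equal(nrow(net$edges), 2)    # (a,b) and (a,c) survive
  expect_setequal(paste(net$edges$from, net$edges$to), c("a b", "a c"))
  expect_equal(sort(net$edges$sign), c(-1, 1))

  # boundary: r exactly at the cutoff is excluded under the strict rule,
  # included under geq
  boundary <- manual_cor_result(tibble::tibble(
    trait_a = "a", trait_b = "b", r = 0.3, p = 0.001))
  expect_equal(nrow(build_network(boundary, ann)$edges), 0)
  expect_equal(nrow(build_network(boundary, ann, r_rule = "geq")$edges), 1)
  # p exactly at the cutoff is excluded
  atp <- manual_cor_result(tibble::tibble(
    trait_a = "a", trait_b = "b", r = 0.9, p = 0.05))
  expect_equal(nrow(build_network(atp, ann)$edges), 0)
})

test_that("unannotated traits abort network assembly with offenders listed", {
  cr <- manual_cor_result(tibble::tibble(
    trait_a = "a", trait_b = "b", r = 0.5, p = 0.01))
  expect_error(build_network(cr, uniform_annotation("a")),
               "b", class = "traitnet_annotation_error")
})

test_that("isolated nodes are dropped unless requested", {
  pairs <- tibble::tibble(trait_a = c("a", "c"), trait_b = c("b", "d"),
                          r = c(0.5, 0.1), p = c(0.01, 0.9))
  cr <- manual_cor_result(pairs)
  ann <- uniform_annotation(c("a", "b", "c", "d"))
  expect_equal(nrow(build_network(cr, ann)$nodes), 2)
  expect_equal(nrow(build_network(cr, ann, keep_isolated = TRUE)$nodes), 4)
})

test_that("filter monotonicity: tightening cutoffs never adds edges", {
  cfg <- small_config(seed = 31)
  pop <- generate_population(cfg)
  z <- standardize_population(pop)
  cr <- correlate_all(z, B = 500, seed = 3)
  base <- build_network(cr, pop$annotation, r_cutoff = 0.3, p_cutoff = 0.05)
  for (rc in c(0.4, 0.5, 0.7)) {
    tighter <- build_network(cr, pop$annotation, r_cutoff = rc,
                             p_cutoff = 0.05)
    expect_true(all(paste(tighter$edges$from, tighter$edges$to) %in%
                      paste(base$edges$from, base$edges$to)))
  }
  lower_p <- build_network(cr, pop$annotation, r_cutoff = 0.3,
                           p_cutoff = 0.01)
  expect_true(all(paste(lower_p$edges$from, lower_p$edges$to) %in%
                    paste(base$edges$from, base$edges$to)))
})

test_that("class-pair summary arithmetic and partition invariants hold", {
  pairs <- tibble::tibble(
    trait_a = c("t1", "t1", "t2", "t3", "p1"),
    trait_b = c("t2", "t3", "t3", "p1", "p2"),
    r = c(0.5, 0.6, 0.7, -0.5, 0.5),
    p = rep(0.01, 5)
  )
  cr <- manual_cor_result(pairs)
  ann <- data.frame(trait = c("t1", "t2", "t3", "p1", "p2"),
                    group = "lipid",
                    class = c("TAG", "TAG", "TAG", "phospholipid",
                              "phospholipid"),
                    subclass = "s")
  net <- build_network(cr, ann)
  s <- class_pair_summary(net)
  expect_equal(sum(s$n_pos + s$n_neg), sum(s$n_edges))
  expect_equal(sum(s$pct_of_edges), 100, tolerance = 1e-9)
  tagtag <- s[s$class_a == "TAG" & s$class_b == "TAG", ]
  expect_equal(tagtag$n_edges, 3)
  expect_equal(tagtag$pct_positive, 100)
  cross <- s[(s$class_a == "TAG") != (s$class_b == "TAG"), ]
  expect_equal(cross$n_edges, 1)
  expect_equal(cross$pct_positive, 0)
  # summary totals equal network stats edge count
  expect_equal(sum(s$n_edges), network_stats(net)$n_edges)

  m <- class_pair_matrix(s)
  expect_equal(m["TAG", "TAG"], 100)
  expect_equal(m["TAG", "phospholipid"], 0)
  expect_equal(m, t(m))
})

test_that("three positive and one negative edge give 75 percent positive", {
  pairs <- tibble::tibble(
    trait_a = c("a1", "a1", "a2", "a2"),
    trait_b = c("b1", "b2", "b1", "b2"),
    r = c(0.5, 0.6, 0.7, -0.5),
    p = rep(0.001, 4)
  )
  ann <- data.frame(trait = c("a1", "a2", "b1", "b2"), group = "lipid",
                    class = c("A", "A", "B", "B"), subclass = "s")
  s <- class_pair_summary(build_network(manual_cor_result(pairs), ann))
  ab <- s[s$class_a == "A" & s$class_b == "B", ]
  expect_equal(ab$pct_positive, 75)
})

test_that("network statistics summarise counts, sign balance, and group shares", {
  empty <- build_network(manual_cor_result(tibble::tibble(
    trait_a = "a", trait_b = "b", r = 0.1, p = 0.9)),
    uniform_annotation(c("a", "b")))
  st0 <- network_stats(empty)
  expect_equal(st0$n_nodes, 0)
  expect_equal(st0$n_edges, 0)
  expect_true(is.na(st0$pct_positive))
  expect_equal(nrow(class_pair_summary(empty)), 0)

  pairs <- tibble::tibble(
    trait_a = paste0("t", 1:10),
    trait_b = paste0("u", 1:10),
    r = c(rep(0.5, 6), rep(-0.5, 4)),
    p = rep(0.01, 10)
  )
  ann <- uniform_annotation(c(paste0("t", 1:10), paste0("u", 1:10)))
  st <- network_stats(build_network(manual_cor_result(pairs), ann))
  expect_equal(st$n_edges, 10)
  expect_equal(st$pct_positive, 60)
  expect_equal(sum(st$group_pair_shares$pct_of_edges), 100, tolerance = 0.01)
})

test_that("exports round-trip through edge TSV and match SIF/GraphML structure", {
  cfg <- small_config(seed = 37)
  pop <- generate_population(cfg)
  z <- standardize_population(pop)
  cr <- correlate_all(z, B = 500, seed = 7)
  net <- build_network(cr, pop$annotation)
  expect_gt(nrow(net$edges), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, format = "edge_tsv")
  back <- read_network_edges(tsv)
  expect_equal(as.data.frame(back), as.data.frame(net$edges))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, format = "sif")
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("\t(pos|neg)\t", lines)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, format = "graphml")
  doc <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(sort(igraph::edge_attr(g, "r")), sort(net$edges$r),
               tolerance = 1e-9)

  expect_error(export_network(net, tsv, format = "gibberish"),
               class = "traitnet_config_error")
})

test_that("tidy and glance views expose edges with classes and headline stats", {
  pairs <- tibble::tibble(trait_a = "a", trait_b = "b", r = 0.5, p = 0.01)
  ann <- data.frame(trait = c("a", "b"), group = "lipid",
                    class = c("TAG", "DGDG"), subclass = "s")
  net <- build_network(manual_cor_result(pairs), ann)
  td <- tidy(net)
  expect_equal(td$class_a, "TAG")
  expect_equal(td$class_b, "DGDG")
  gl <- glance(net)
  expect_equal(gl$n_edges, 1)
  expect_equal(gl$pct_positive, 100)
})
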