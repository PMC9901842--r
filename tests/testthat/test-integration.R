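test_that("GMT parsing validates structure and round-trips", {
  gmt <- read_gmt(fixture_path("table3.gmt"))
  expect_length(gmt, 17)
  expect_true(all(c("hsa04080", "hsa04977") %in% names(gmt)))
  expect_setequal(gmt$hsa04918, c("GPX3", "C01060"))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\tdesc\tA\tB", "broken_line_without_tabs"), bad)
  expect_error(read_gmt(bad), "line 2")
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gmt, out)
  expect_identical(read_gmt(out), gmt)
})

test_that("term refinement collapses by transitive Jaccard similarity", {
  disjoint <- list(t1 = c("a", "b"), t2 = c("c", "d"))
  expect_identical(refine_terms(disjoint)$sets, disjoint)
  dup <- list(t2 = c("a", "b", "c"), t1 = c("a", "b", "c"))
  r <- refine_terms(dup)
  expect_length(r$sets, 1)
  expect_identical(names(r$sets), "t1")      # lexicographic tie-break
  # chain: J(A,B) and J(B,C) > 0.7 but J(A,C) < 0.7 -> one cluster
  chain <- list(A = as.character(1:10),
                B = as.character(c(1:9, 11)),
                C = as.character(c(1:8, 11, 12)))
  rc <- refine_terms(chain, 0.7)
  expect_length(rc$sets, 1)
  expect_identical(unique(rc$mapping$representative), "A")
  # determinism under input reordering (same representative set)
  rc2 <- refine_terms(chain[c(3, 1, 2)], 0.7)
  expect_identical(names(rc2$sets), names(rc$sets))
})

test_that("element mapping joins layers onto pathways through the GMT", {
  gmt <- read_gmt(fixture_path("table3.gmt"))
  els <- utils::read.delim(fixture_path("table3_elements.tsv"))
  m <- map_elements(els, gmt)
  expect_identical(m$pathways[[which(m$element_id == "PLG")]], "hsa04080")
  # SNP mapped through its gene: SCARB1 sits in six pathways
  expect_identical(m$n_pathways[m$element_id == "rs61941687"], 6L)
  expect_setequal(m$pathways[[which(m$element_id == "rs61941687")]],
                  c("hsa04913", "hsa04915", "hsa04975", "hsa04976",
                    "hsa04977", "hsa04979"))
  # unmapped element kept with empty set and a warning
  orphan <- rbind(els, data.frame(element_id = "NOSUCH",
                                  layer = "proteome",
                                  mapped_gene = NA))
  expect_warning(m2 <- map_elements(orphan, gmt), "no pathway")
  expect_identical(m2$n_pathways[m2$element_id == "NOSUCH"], 0L)
  expect_error(map_elements(data.frame(element_id = "x", layer = "bogus"),
                            gmt), "unknown layer")
})

test_that("graph construction follows the pair/self-loop rules", {
  mapped <- data.frame(element_id = c("e1", "e2"),
                       layer = c("proteome", "metabolome"),
                       mapped_gene = NA, n_pathways = c(3L, 1L))
  mapped$pathways <- list(c("A", "B", "C"), "D")
  g <- build_graph(mapped)
  el <- igraph::as_edgelist(g)
  expect_equal(igraph::ecount(g), 4)          # triangle + one self-loop
  expect_identical(sum(el[, 1] == el[, 2]), 1L)
  expect_setequal(igraph::E(g)$element[el[, 1] != el[, 2]], "e1")
  expect_identical(igraph::E(g)$layer[el[, 1] == el[, 2]], "metabolome")
})

test_that("edge count obeys the combinatorial identity on random inputs", {
  for (s in 1:25) {
    mapped <- random_mapped_elements(n_elements = sample(3:15, 1),
                                     n_pathways = sample(4:8, 1),
                                     seed = 1000 + s)
    g <- build_graph(mapped)
    k <- mapped$n_pathways
    expect_equal(igraph::ecount(g), sum(choose(k, 2) + (k == 1)))
    # summaries invariant to element order
    perm <- sample(nrow(mapped))
    s1 <- summarize_graph(build_graph(mapped))
    s2 <- summarize_graph(build_graph(mapped[perm, ]))
    expect_equal(s1$assortativity, s2$assortativity)
    expect_equal(s1$size, s2$size)
    expect_equal(s1$hub_counts, s2$hub_counts)
  }
})

test_that("assortativity matches closed forms and the correlation oracle", {
  star <- data.frame(element_id = paste0("e", 1:5), layer = "proteome",
                     mapped_gene = NA, n_pathways = 2L)
  star$pathways <- lapply(paste0("leaf", 1:5), function(l) c("hub", l))
  s <- summarize_graph(build_graph(star))
  expect_equal(s$assortativity, -1)
  expect_identical(s$size, 5L)
  path4 <- data.frame(element_id = paste0("e", 1:3), layer = "gwas",
                      mapped_gene = NA, n_pathways = 2L)
  path4$pathways <- list(c("A", "B"), c("B", "C"), c("C", "D"))
  expect_equal(summarize_graph(build_graph(path4))$assortativity, -0.5)
  # random multigraphs vs endpoint-degree correlation oracle and igraph
  for (s_ in 1:40) {
    mapped <- random_mapped_elements(sample(3:10, 1), sample(3:8, 1),
                                     seed = 2000 + s_)
    g <- build_graph(mapped)
    summ <- summarize_graph(g)
    el <- igraph::as_edgelist(g)
    nl <- el[el[, 1] != el[, 2], , drop = FALSE]
    deg <- summ$centrality$centrality
    names(deg) <- summ$centrality$pathway
    oracle <- assortativity_oracle(deg[nl[, 1]], deg[nl[, 2]])
    if (is.na(oracle)) {
      expect_false(summ$assortativity_defined)
    } else {
      expect_equal(summ$assortativity, oracle, tolerance = 1e-10)
      gs <- igraph::delete_edges(g, which(el[, 1] == el[, 2]))
      expect_equal(summ$assortativity,
                   igraph::assortativity_degree(gs), tolerance = 1e-10)
    }
  }
  # empty graph: size 0, no hubs, assortativity undefined
  empty <- summarize_graph(build_graph(random_mapped_elements(0, 3, 1)))
  expect_identical(empty$size, 0L)
  expect_true(all(empty$hub_counts == 0))
  expect_false(empty$assortativity_defined)
})

test_that("self-loop weighting of centrality is configurable", {
  mapped <- data.frame(element_id = c("e1", "e2"), layer = "proteome",
                       mapped_gene = NA, n_pathways = c(1L, 2L))
  mapped$pathways <- list("A", c("A", "B"))
  g <- build_graph(mapped)
  c0 <- summarize_graph(g, loop_weight = 0)$centrality
  c2 <- summarize_graph(g, loop_weight = 2)$centrality
  expect_equal(c0$centrality[c0$pathway == "A"], 1)
  expect_equal(c2$centrality[c2$pathway == "A"], 3)
})

test_that("intersection report counts triple-layer pathways", {
  gmt <- read_gmt(fixture_path("table3.gmt"))
  els <- utils::read.delim(fixture_path("table3_elements.tsv"))
  rep_ <- intersection_report(map_elements(els, gmt))
  expect_identical(rep_$triple_layer_count, 2L)
  # a single-layer input has no triple intersections
  solo <- map_elements(els[els$layer == "metabolome", ], gmt)
  expect_identical(intersection_report(solo)$triple_layer_count, 0L)
  # adding one metabolite to an arachidonic-acid-like proteome+gwas
  # pathway creates a third triple
  gmt2 <- gmt
  gmt2$hsa00590 <- c(gmt2$hsa00590, "C00219")
  els2 <- rbind(els, data.frame(element_id = "C00219",
                                layer = "metabolome", mapped_gene = NA))
  rep2 <- intersection_report(map_elements(els2, gmt2))
  expect_identical(rep2$triple_layer_count, 3L)
})
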