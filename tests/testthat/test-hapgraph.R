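test_that("edge weight follows 1/(-log(1-M)) with clamping", {
  ## -log(1 - (1 - 1/e)) = 1
  expect_equal(edge_weight(1 - exp(-1)), 1.0, tolerance = 1e-9)
  expect_equal(edge_weight(0.9), 1 / (-log(0.1)), tolerance = 1e-12)
  expect_equal(edge_weight(0.9), 0.43429, tolerance = 1e-4)
  ## M = 1 clamps to 1 - eps
  expect_equal(edge_weight(1), 1 / (-log(1e-9)), tolerance = 1e-12)
  expect_equal(edge_weight(1), 0.04825, tolerance = 1e-3)
  expect_error(edge_weight(1.2), "outside")
  expect_error(edge_weight(-0.1), "outside")
})

test_that("edge weight is strictly decreasing and non-negative on (0,1)", {
  grid <- seq(0.001, 0.999, by = 0.001)
  w <- edge_weight(grid)
  expect_true(all(w >= 0))
  expect_true(all(diff(w) < 0))
})

test_that("switch counts enumerate multiset overlap of pairs", {
  expect_equal(switch_count(c("A", "B"), c("A", "B")), 0L)
  expect_equal(switch_count(c("A", "B"), c("B", "A")), 0L)  # unordered
  expect_equal(switch_count(c("A", "B"), c("A", "C")), 1L)
  expect_equal(switch_count(c("A", "A"), c("B", "C")), 2L)
  expect_equal(switch_count(c("A", "A"), c("A", "B")), 1L)
  expect_equal(switch_count(c("A", "A"), c("A", "A")), 0L)
  expect_equal(switch_count(c("A", "A"), c("B", "B")), 2L)
})

test_that("a one-gene graph has source, sink and two edges; best state maximizes M", {
  cand <- rbind(score_row("g1", "A", "B", M = 0.6),
                score_row("g1", "A", "C", M = 0.8))
  g <- build_gene_graph("g1", cand)
  e <- graph_edges(g)
  expect_equal(nrow(e), 4L)  # 2 source + 2 sink edges (one per state)
  calls <- best_haplotype_path(g)
  expect_equal(calls$pair, "A/C")  # w decreasing in M -> max-M state
  expect_equal(calls, brute_force_path(g))
})

test_that("inter-gene edge weights compose mean-M transform plus switch penalty", {
  cand <- rbind(score_row("g1", "A", "B", M = 0.6),
                score_row("g1", "C", "D", M = 0.6),
                score_row("g2", "A", "B", M = 0.8),
                score_row("g2", "A", "D", M = 0.8))
  g <- build_gene_graph(c("g1", "g2"), cand, penalty = 0.01)
  e <- graph_edges(g)
  inter <- e[e$from_gene == "g1" & e$to_gene == "g2", ]
  expect_equal(nrow(inter), 4L)
  base <- edge_weight(mean(c(0.6, 0.8)))
  expect_equal(inter[inter$from_state == "A/B" & inter$to_state == "A/B",
                     weight], base)
  expect_equal(inter[inter$from_state == "A/B" & inter$to_state == "A/D",
                     weight], base + 0.01)
  expect_equal(inter[inter$from_state == "C/D" & inter$to_state == "A/B",
                     weight], base + 0.02)
  expect_equal(inter[inter$from_state == "C/D" & inter$to_state == "A/D",
                     weight], base + 0.01)
})

test_that("the switch penalty keeps the path on the neighbours' pair", {
  ## gene2's marginally best pair differs from its neighbours by 2 switches;
  ## with a penalty large enough the path keeps the neighbours' pair
  cand <- rbind(score_row("g1", "A", "B", M = 0.9),
                score_row("g2", "A", "B", M = 0.88),
                score_row("g2", "C", "D", M = 0.9),
                score_row("g3", "A", "B", M = 0.9))
  gain <- edge_weight(mean(c(0.9, 0.88))) - edge_weight(0.9)
  g_small <- build_gene_graph(c("g1", "g2", "g3"), cand, penalty = 0)
  expect_equal(best_haplotype_path(g_small)$pair[2], "C/D")
  g_big <- build_gene_graph(c("g1", "g2", "g3"), cand, penalty = gain)
  expect_equal(best_haplotype_path(g_big)$pair[2], "A/B")
  expect_equal(best_haplotype_path(g_big),
               brute_force_path(g_big))
})

test_that("a read-less gene gets a wildcard state that is switch-free", {
  cand <- rbind(score_row("g1", "A", "B", M = 0.7),
                score_row("g3", "A", "B", M = 0.7))
  g <- build_gene_graph(c("g1", "g2", "g3"), cand)
  calls <- best_haplotype_path(g)
  expect_true(calls$wildcard[2])
  expect_equal(calls$pair[2], "*")
  expect_equal(calls$pair[c(1, 3)], c("A/B", "A/B"))
  ## wildcard edges take the neighbour's rate only, no penalty
  e <- graph_edges(g)
  expect_equal(e[e$from_gene == "g1" & e$to_gene == "g2", "weight"][[1]],
               edge_weight(0.7))
})

test_that("empty gene list is rejected", {
  expect_error(build_gene_graph(character(0), score_row("g", "A", "A", 0.5)),
               "empty")
})

test_that("dynamic programming equals brute force and igraph Dijkstra", {
  skip_if_not_installed("igraph")
  set.seed(2024)
  for (i in 1:60) {
    g <- random_graph_instance(n_genes = sample(2:5, 1),
                               n_states = sample(1:4, 1),
                               penalty = sample(c(0, 0.0028, 0.05), 1))
    dp <- best_haplotype_path(g)
    bf <- brute_force_path(g)
    expect_equal(attr(dp, "cost"), attr(bf, "cost"), tolerance = 1e-9)
    expect_equal(dp$pair, bf$pair)
    ## independent check with igraph's Dijkstra on the exported edge list
    ig <- as_igraph(g)
    d <- igraph::distances(ig, v = ".source", to = ".sink", mode = "out",
                           weights = igraph::E(ig)$weight)[1, 1]
    expect_equal(unname(d), attr(dp, "cost"), tolerance = 1e-9)
  }
})

test_that("zero penalty reduces to per-gene greedy max-M selection", {
  set.seed(7)
  for (i in 1:20) {
    g <- random_graph_instance(n_genes = 4, n_states = 3, penalty = 0)
    calls <- best_haplotype_path(g)
    for (j in seq_along(g$genes)) {
      st <- g$states[[j]]
      expect_equal(calls$M[j], max(st$M), tolerance = 1e-12)
    }
  }
})

test_that("a very large penalty forces a constant pair when one is shared", {
  cand <- rbind(score_row("g1", "A", "B", M = 0.5),
                score_row("g1", "A", "C", M = 0.9),
                score_row("g2", "A", "B", M = 0.5),
                score_row("g2", "B", "C", M = 0.9),
                score_row("g3", "A", "B", M = 0.5))
  g <- build_gene_graph(c("g1", "g2", "g3"), cand, penalty = 1e3)
  calls <- best_haplotype_path(g)
  expect_equal(unique(calls$pair), "A/B")
})

test_that("cost ties prefer homozygous states, then lexicographic labels", {
  cand <- rbind(score_row("g1", "B", "B", M = 0.8),
                score_row("g1", "A", "B", M = 0.8))
  g <- build_gene_graph("g1", cand, penalty = 0)
  ## equal cost: homozygous {B,B} preferred over heterozygous {A,B}
  expect_equal(best_haplotype_path(g)$pair, "B/B")
  expect_equal(brute_force_path(g)$pair, "B/B")
  cand2 <- rbind(score_row("g1", "A", "C", M = 0.8),
                 score_row("g1", "A", "B", M = 0.8))
  g2 <- build_gene_graph("g1", cand2, penalty = 0)
  expect_equal(best_haplotype_path(g2)$pair, "A/B")
})

test_that("brute force refuses oversized instances", {
  cand <- data.table::rbindlist(lapply(1:25, function(i)
    rbind(score_row(sprintf("g%02d", i), "A", "B", 0.5),
          score_row(sprintf("g%02d", i), "A", "C", 0.6))))
  g <- build_gene_graph(sprintf("g%02d", 1:25), cand)
  expect_error(brute_force_path(g), "too large")
})
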