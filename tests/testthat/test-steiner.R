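test_that("a unique connecting path is returned verbatim", {
  g <- path_graph(c("A", "B", "C", "D", "E"))
  r <- approximate_steiner_tree(g, c("A", "E"))
  expect_equal(r$n_nodes, 5)
  expect_equal(r$n_edges, 4)
  expect_equal(r$connectors, c("B", "C", "D"))
  expect_equal(r$terminals_included, c("A", "E"))
  b <- brute_force_steiner(g, c("A", "E"))
  expect_equal(canonical_el(b$tree), canonical_el(r$tree))
})

test_that("a forced hub becomes the sole connector of star terminals", {
  g <- star_graph_named("H", c("T1", "T2", "T3"))
  r <- approximate_steiner_tree(g, c("T1", "T2", "T3"))
  expect_equal(r$n_nodes, 4)
  expect_equal(r$n_edges, 3)
  expect_equal(r$connectors, "H")
})

test_that("exhaustive search solves small hand-checkable instances", {
  # triangle a-b-c with pendant terminals t1-a, t2-b
  g <- interactome(c("A", "B", "C", "T1", "T2"),
                   c("B", "C", "A", "A", "B"))
  r <- brute_force_steiner(g, c("T1", "T2"))
  expect_equal(r$n_edges, 3)  # t1-a-b-t2
  expect_setequal(r$connectors, c("A", "B"))
  # adjacent terminals need no connector
  r2 <- brute_force_steiner(g, c("A", "B"))
  expect_equal(r2$n_edges, 1)
  expect_length(r2$connectors, 0)
  big <- path_graph(sprintf("N%02d", 1:17))
  expect_error(brute_force_steiner(big, c("N01", "N17")), "too large")
})

test_that("every result satisfies the tree identity and spans reachable terminals", {
  set.seed(31)
  for (rep in 1:20) {
    g <- random_connected_graph(12, 0.3)
    terms <- sample(igraph::V(g)$name, 4)
    r <- approximate_steiner_tree(g, terms)
    expect_equal(igraph::ecount(r$tree), igraph::vcount(r$tree) - 1)
    expect_true(igraph::is_connected(r$tree))
    expect_true(all(terms %in% igraph::V(r$tree)$name))
    expect_setequal(c(r$terminals_included, r$connectors),
                    igraph::V(r$tree)$name)
    b <- brute_force_steiner(g, terms)
    expect_lte(r$n_edges, 2 * b$n_edges)
  }
})

test_that("identical inputs give identical trees and exports", {
  set.seed(17)
  g <- random_connected_graph(14, 0.25)
  terms <- sample(igraph::V(g)$name, 5)
  r1 <- approximate_steiner_tree(g, terms)
  r2 <- approximate_steiner_tree(g, terms)
  expect_equal(canonical_el(r1$tree), canonical_el(r2$tree))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  export_subnetwork(r1, f1, "tsv"); export_subnetwork(r2, f2, "tsv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("shortcut edges between tree nodes never worsen the tree", {
  set.seed(41)
  worse <- 0
  for (rep in 1:20) {
    g <- random_connected_graph(12, 0.25)
    terms <- sample(igraph::V(g)$name, 4)
    r <- approximate_steiner_tree(g, terms)
    tn <- igraph::V(r$tree)$name
    pair <- NULL
    for (i in seq_along(tn)) {
      for (j in seq_along(tn)) {
        if (j > i && !igraph::are_adjacent(g, tn[i], tn[j])) {
          pair <- c(tn[i], tn[j]); break
        }
      }
      if (!is.null(pair)) break
    }
    if (is.null(pair)) next
    g2 <- igraph::add_edges(g, match(pair, igraph::V(g)$name))
    r2 <- approximate_steiner_tree(g2, terms)
    if (r2$n_edges > r$n_edges) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("absent and disconnected terminals are reported, not fatal", {
  g <- merge_networks(list(path_graph(c("A", "B", "C")),
                           path_graph(c("X", "Y", "Z"))))
  expect_warning(r <- approximate_steiner_tree(g, c("A", "C", "X", "GHOST")),
                 "absent")
  expect_setequal(r$unreachable_terminals, c("GHOST", "X"))
  expect_setequal(r$terminals_included, c("A", "C"))
  expect_error(approximate_steiner_tree(g, c("A", "X")), "nothing to connect")
  expect_error(suppressWarnings(
    approximate_steiner_tree(g, c("GHOST1", "GHOST2"))), "nothing to connect")
})

test_that("forest mode connects terminals in every qualifying component", {
  g <- merge_networks(list(path_graph(c("A", "B", "C")),
                           path_graph(c("X", "Y", "Z"))))
  r <- approximate_steiner_tree(g, c("A", "C", "X", "Z"), mode = "forest")
  expect_setequal(r$terminals_included, c("A", "C", "X", "Z"))
  expect_setequal(r$connectors, c("B", "Y"))
  expect_equal(r$n_edges, 4)  # two 2-edge paths
})

test_that("edge induction restores non-tree interactome edges", {
  # cycle A-B-C-D-A: tree uses 3 edges, induction restores the 4th
  g <- interactome(c("A", "B", "C", "D"), c("B", "C", "D", "A"))
  r <- approximate_steiner_tree(g, c("A", "B", "C", "D"),
                                induce_edges = TRUE)
  expect_equal(igraph::ecount(r$tree), 3)
  expect_equal(r$n_edges, 4)
  expect_equal(igraph::ecount(r$subnetwork), 4)
})

test_that("connector extraction matches the seed complement", {
  g <- path_graph(c("A", "B", "C", "D", "E"))
  r <- approximate_steiner_tree(g, c("A", "E"))
  expect_equal(extract_connectors(r, c("A", "E")), c("B", "C", "D"))
  expect_equal(extract_connectors(r, r$terminals_included), r$connectors)
  star <- star_graph_named("H", c("T1", "T2"))
  rs <- approximate_steiner_tree(star, c("H", "T1", "T2"))
  expect_length(extract_connectors(rs, c("H", "T1", "T2")), 0)
})

test_that("neighborhood seed fractions match planted ground truth", {
  star <- star_graph_named("H", c("S1", "S2", "S3"))
  r <- key_node_neighborhood(star, "H", c("S1", "S2", "S3"))
  expect_equal(r$seed_fraction, 1)
  # degenerate: focus with no outside interactors
  expect_warning(
    r0 <- key_node_neighborhood(star, c("H", "S1", "S2", "S3"),
                                c("S1", "S2")),
    "no interactors")
  expect_equal(r0$seed_fraction, 0)
  expect_error(key_node_neighborhood(star, character(0), "S1"), "empty")
  expect_error(key_node_neighborhood(star, "NOPE", "S1"), "absent")

  # 69 planted neighbors of which 54 are seeds
  nb <- sprintf("N%02d", 1:69)
  g <- star_graph_named("HUB", nb)
  rep69 <- key_node_neighborhood(g, "HUB", nb[1:54])
  expect_length(rep69$neighbors, 69)
  expect_equal(rep69$seed_fraction, 54 / 69)
  expect_equal(rep69$seed_fraction, 0.78, tolerance = 0.01)
})
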