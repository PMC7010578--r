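test_that("hypergeometric tail matches hand-derived small cases", {
  expect_equal(hypergeom_sf(0, 5, 4, 10), 1)
  expect_equal(hypergeom_sf(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_sf(2, 2, 2, 4), 1 / 6)
})

test_that("hypergeometric tail rejects invariant violations by name", {
  expect_error(hypergeom_sf(3, 2, 5, 10), "k <= min\\(K, n\\)")
  expect_error(hypergeom_sf(1, 11, 5, 10), "K <= N")
  expect_error(hypergeom_sf(1, 5, 11, 10), "n <= N")
  expect_error(hypergeom_sf(-1, 5, 5, 10), "non-negative")
})

test_that("tail probability is non-increasing in the overlap count", {
  for (K in c(3, 6)) for (n in c(4, 7)) {
    ks <- 0:min(K, n)
    p <- vapply(ks, hypergeom_sf, numeric(1), K = K, n = n, N = 12)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  # worked step-up: sorted p*m/i = (0.015, 0.045, 0.04); cummin from the
  # tail caps the middle value at 0.04
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03)),
               c(0.015, 0.04, 0.04))
  expect_error(bh_adjust(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("BH output is permutation-equivariant, bounded, and >= raw p", {
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(sample(1:15, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q >= 0 & q <= 1))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("single-term testing restricts to the universe before counting", {
  seeds <- seed_list(c("A", "B"))
  r <- enrich_term(seeds, gene_set("S", c("A", "B")), c("A", "B", "C", "D"))
  expect_equal(unlist(r[c("k", "K", "n", "N")]),
               c(k = 2, K = 2, n = 2, N = 4))
  expect_equal(r$p_value, 1 / 6)
  expect_equal(r$seed_genes, "A,B")
  # disjoint set
  r2 <- enrich_term(seeds, gene_set("S", c("X", "Y")), c("A", "B", "X", "Y"))
  expect_equal(r2$p_value, 1)
  # set entirely outside the universe degenerates to K = 0, p = 1
  r3 <- enrich_term(seeds, gene_set("S", c("Z1", "Z2")), c("A", "B", "C"))
  expect_equal(unlist(r3[c("k", "K")]), c(k = 0, K = 0))
  expect_equal(r3$p_value, 1)
  expect_error(enrich_term(seeds, gene_set("S", "A"), character(0)),
               "universe")
})

test_that("collection-level analysis filters, adjusts and orders correctly", {
  set.seed(11)
  universe <- sprintf("U%03d", 1:100)
  planted <- gene_set("PLANTED", universe[1:10])
  nulls <- lapply(1:9, function(i)
    gene_set(sprintf("NULL%02d", i), sample(universe[31:100], 8)))
  col <- gene_set_collection(c(list(planted), nulls))
  seeds <- seed_list(c(universe[1:6], universe[91:98]))

  res <- run_enrichment(seeds, col, universe = universe,
                        min_seed_genes = 5, fdr_threshold = 0.05)
  expect_equal(res$set_id, "PLANTED")
  expect_equal(res$k, 6)

  expect_equal(nrow(run_enrichment(seeds, col, universe = universe,
                                   fdr_threshold = 0)), 0)
  all_rows <- run_enrichment(seeds, col, universe = universe,
                             min_seed_genes = 1, fdr_threshold = 1)
  # BH was applied across all 10 tested sets, not only survivors
  expect_equal(res$fdr, all_rows$fdr[all_rows$set_id == "PLANTED"])
  # min_seed_genes = 1 + threshold 1 keeps every set with any seed overlap
  with_hit <- sum(vapply(col$sets, function(s)
    length(intersect(s$members, seeds$genes)) >= 1, logical(1)))
  expect_equal(nrow(all_rows), with_hit)
  expect_false(is.unsorted(all_rows$p_value))
  # ties broken lexicographically by set_id
  tied <- all_rows[all_rows$p_value == max(all_rows$p_value), "set_id"]
  expect_identical(tied, sort(tied))
  # with every set overlapping the seeds, no filtering returns them all
  col2 <- gene_set_collection(lapply(1:4, function(i)
    gene_set(sprintf("T%d", i), c(universe[1], sample(universe[20:80], 5)))))
  expect_equal(nrow(run_enrichment(seeds, col2, universe = universe,
                                   min_seed_genes = 1, fdr_threshold = 1)),
               length(col2$sets))
  expect_error(run_enrichment(seeds, col, min_seed_genes = 0), ">= 1")
  expect_error(run_enrichment(seeds, col, fdr_threshold = 1.5), "\\[0, 1\\]")
})

test_that("two-sided testing and subset pruning are available", {
  universe <- sprintf("U%03d", 1:40)
  seeds <- seed_list(universe[1:10])
  big <- gene_set("BIG", universe[1:8])
  nested <- gene_set("NESTED", universe[1:4])
  col <- gene_set_collection(list(big, nested))
  res2 <- run_enrichment(seeds, col, universe = universe, min_seed_genes = 1,
                         fdr_threshold = 1, alternative = "two.sided")
  expect_equal(nrow(res2), 2)
  pruned <- run_enrichment(seeds, col, universe = universe,
                           min_seed_genes = 1, fdr_threshold = 1,
                           prune_subsets = TRUE)
  expect_equal(pruned$set_id, "BIG")
})
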