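test_that("edge-list loading drops self-loops and duplicate edges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta", "a\ta", "b\tc"), path)
  g <- load_edge_list(path)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2)
  expect_equal(attr(g, "n_self_loops"), 1L)
  expect_equal(attr(g, "n_duplicates"), 1L)
  expect_equal(unname(igraph::degree(g)[c("a", "b")]), c(1, 2))
})

test_that("malformed and empty edge lists raise informative errors", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "a\tb", "lonely"), bad)
  expect_error(load_edge_list(bad), "line 3")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only a comment", empty)
  expect_error(load_edge_list(empty), "empty")
})

test_that("a generated edge list round-trips through write and load", {
  g <- random_test_graph(120, 0.05, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- load_edge_list(path)
  key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(g2), key(g))
})

test_that("multi-source min distances match per-source BFS", {
  g <- path_graph()
  expect_equal(all_pairs_min_distance(g, "a"), c(a = 0, b = 1, c = 2))
  expect_equal(all_pairs_min_distance(g, c("a", "c")), c(a = 0, b = 1, c = 0))
  # random graph against the scratch BFS oracle
  g <- random_test_graph(100, 0.04, seed = 3)
  nodes <- igraph::V(g)$name
  edges <- igraph::as_edgelist(g)
  sources <- nodes[c(1, 17, 40)]
  got <- all_pairs_min_distance(g, sources)
  per_source <- sapply(sources, function(s) bfs_oracle(edges, nodes, s))
  expect_equal(got[nodes], apply(per_source, 1, min)[nodes])
})

test_that("distances are symmetric on sampled pairs", {
  g <- random_test_graph(80, 0.05, seed = 9)
  nodes <- igraph::V(g)$name
  pairs <- netrepurpose:::with_seed(1, replicate(25, sample(nodes, 2)))
  for (i in seq_len(ncol(pairs))) {
    expect_equal(
      unname(all_pairs_min_distance(g, pairs[1, i])[pairs[2, i]]),
      unname(all_pairs_min_distance(g, pairs[2, i])[pairs[1, i]]))
  }
})

test_that("degree bins partition nodes and respect the minimum size", {
  fx <- study_fixture()
  bins <- fx$bins
  expect_setequal(names(bins$bin_of), igraph::V(fx$graph)$name)
  sizes <- lengths(bins$members)
  expect_true(all(sizes >= 100))
  # within a bin, degrees form a contiguous ascending block
  deg <- igraph::degree(fx$graph)
  ranges <- t(vapply(bins$members, function(m) range(deg[m]), c(0, 0)))
  ord <- order(ranges[, 1])
  expect_true(all(diff(ranges[ord, 1]) >= 0))
})

test_that("degree-matched sampling is deterministic, distinct, bin-faithful", {
  fx <- study_fixture()
  template <- fx$planted[1:5]
  s1 <- sample_degree_matched(fx$graph, template, rng_seed = 11, bins = fx$bins)
  s2 <- sample_degree_matched(fx$graph, template, rng_seed = 11, bins = fx$bins)
  expect_identical(s1, s2)
  expect_equal(length(s1), 5)
  expect_false(anyDuplicated(s1) > 0)
  expect_true(all(s1 %in% igraph::V(fx$graph)$name))
  # bin multiset of the sample matches the template's
  expect_equal(sort(unname(fx$bins$bin_of[s1])),
               sort(unname(fx$bins$bin_of[template])))
})

test_that("sampling the whole node set returns a permutation of it", {
  g <- interactome(data.frame(a = c("a", "b", "c"), b = c("b", "c", "d")))
  all_nodes <- igraph::V(g)$name
  out <- sample_degree_matched(g, all_nodes, rng_seed = 2, min_bin_size = 1e6)
  expect_setequal(out, all_nodes)
})

test_that("sampled sets track the template's mean degree", {
  fx <- study_fixture()
  deg <- igraph::degree(fx$graph)
  # bin width proportional to the fixture's size: 100-node bins are
  # interactome-scale granularity, 50 is the equivalent on 1000 nodes
  bins <- degree_bins(fx$graph, min_size = 50)
  template <- netrepurpose:::with_seed(5, sample(names(deg), 12))
  means <- vapply(1:1000, function(i)
    mean(deg[sample_degree_matched(fx$graph, template, rng_seed = i,
                                   bins = bins)]), 0)
  expect_lt(abs(mean(means) - mean(deg[template])) / mean(deg[template]), 0.15)
})

test_that("LCC localization flags a planted clique and not scattered genes", {
  g <- netrepurpose:::with_seed(21, {
    gg <- igraph::sample_gnp(1500, 0.002)
    igraph::V(gg)$name <- sprintf("v%04d", 1:1500)
    gg
  })
  clique_nodes <- sprintf("v%04d", 1:15)
  g <- igraph::add_edges(g, as.vector(utils::combn(clique_nodes, 2)))
  g <- igraph::simplify(g)
  res <- lcc_significance(g, clique_nodes, n_perm = 200, rng_seed = 4)
  expect_equal(res$observed_lcc, 15L)
  expect_lte(res$empirical_p, 0.01)
  # an independent set in a star-free tree induces singletons
  tree <- interactome(data.frame(from = c("r", "r", "x", "y"),
                                 to = c("x", "y", "x1", "y1")))
  res2 <- lcc_significance(tree, c("r", "x1", "y1"), n_perm = 20,
                           rng_seed = 1, null = "uniform")
  expect_equal(res2$observed_lcc, 1L)
})

test_that("degenerate LCC null yields empirical p of 1 and undefined z", {
  pn <- permutation_null(rep(5, 100))
  expect_equal(empirical_p(pn, 5, "geq"), 1.0)
  expect_true(is.na(permutation_z(5, pn)))
})

test_that("LCC significance is invariant to gene-set order", {
  fx <- study_fixture()
  genes <- fx$planted
  a <- lcc_significance(fx$graph, genes, n_perm = 50, rng_seed = 3,
                        bins = fx$bins)
  b <- lcc_significance(fx$graph, rev(genes), n_perm = 50, rng_seed = 3,
                        bins = fx$bins)
  expect_equal(a$empirical_p, b$empirical_p)
  expect_equal(a$observed_lcc, b$observed_lcc)
})

test_that("GMT and plain gene-set files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# benchmark", "g1", "g2", "g1"), txt)
  expect_equal(read_gene_set(txt), c("g1", "g2"))
})
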