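test_that("Wang similarity reproduces the hand-evaluated two-leaf DAG", {
  dag <- hand_dag()
  expect_equal(wang_term_similarity(dag, "a", "a"), 1)
  expect_equal(wang_term_similarity(dag, "r", "r"), 1)
  # S_a = {a: 1, r: 0.8}, SV = 1.8 each; sim = (0.8 + 0.8) / 3.6 = 4/9
  expect_equal(wang_term_similarity(dag, "a", "b"), 4 / 9)
  expect_equal(wang_term_similarity(dag, "a", "b"),
               wang_term_similarity(dag, "b", "a"))
})

test_that("Wang similarity errors across namespaces and on unknown terms", {
  dag <- go_dag(terms = c("p", "q"), namespace = c(p = "BP", q = "MF"),
                parents = data.frame(term = character(),
                                     parent = character(),
                                     relation = character()))
  expect_error(wang_term_similarity(dag, "p", "q"), "namespace")
  expect_error(wang_term_similarity(dag, "p", "zz"), "unknown term")
})

test_that("similarity to an ancestor grows as the chain shortens", {
  # linear ontology t4 -> t3 -> t2 -> t1 (root)
  dag <- go_dag(terms = paste0("t", 1:4),
                namespace = setNames(rep("BP", 4), paste0("t", 1:4)),
                parents = data.frame(term = paste0("t", 4:2),
                                     parent = paste0("t", 3:1),
                                     relation = "is_a"))
  sims <- vapply(paste0("t", 1:3), function(t)
    wang_term_similarity(dag, "t4", t), 0)
  expect_true(all(diff(sims) > 0))
  expect_gt(min(sims), 0)  # root is always shared within a namespace
})

test_that("Wang similarity agrees with an independent re-implementation", {
  fx <- study_fixture()
  dag <- fx$dag
  bp_terms <- dag$terms[dag$namespace[dag$terms] == "BP"]
  edges <- do.call(rbind, lapply(bp_terms, function(t) {
    pr <- dag$parents[[t]]
    if (is.null(pr) || !nrow(pr)) return(NULL)
    data.frame(term = t, pr)
  }))
  pairs <- netrepurpose:::with_seed(3, replicate(15, sample(bp_terms, 2)))
  for (i in seq_len(ncol(pairs))) {
    expect_equal(
      wang_term_similarity(dag, pairs[1, i], pairs[2, i]),
      naive_wang(edges, dag$weights, pairs[1, i], pairs[2, i]))
  }
})

test_that("gene-level BMA reproduces the hand-worked aggregation", {
  dag <- hand_dag()
  annot <- annotation_map(c("g1", "g1", "g2", "g3"),
                          c("a", "b", "a", "b"), dag)
  # identical term sets
  expect_equal(bma_gene_similarity(dag, annot, "g1", "g1", "BP"), 1)
  # T1 = {a, b}, T2 = {a}: (avg(1, 4/9) + 1) / 2 = 0.861111...
  expect_equal(bma_gene_similarity(dag, annot, "g1", "g2", "BP"),
               (mean(c(1, 4 / 9)) + 1) / 2)
  # unannotated gene: missing, not zero
  expect_true(is.na(bma_gene_similarity(dag, annot, "g1", "nope", "BP")))
})

test_that("BMA lies between the min and max of the pairwise matrix", {
  fx <- study_fixture()
  genes <- annotated_genes(fx$annot)
  netrepurpose:::with_seed(8, {
    for (i in 1:10) {
      gs <- sample(genes, 2)
      t1 <- fx$annot$BP[[gs[1]]]; t2 <- fx$annot$BP[[gs[2]]]
      if (is.null(t1) || is.null(t2)) next
      M <- outer(t1, t2, Vectorize(function(x, y)
        wang_term_similarity(fx$dag, x, y)))
      v <- bma_gene_similarity(fx$dag, fx$annot, gs[1], gs[2], "BP")
      expect_gte(v, min(M)); expect_lte(v, max(M))
    }
  })
})

test_that("set similarity is invariant to gene order and self-similarity is 1", {
  fx <- study_fixture()
  A <- fx$planted[1:6]; B <- fx$planted[7:15]
  s1 <- gene_set_similarity(fx$dag, fx$annot, A, B, "BP")
  s2 <- gene_set_similarity(fx$dag, fx$annot, rev(A), sample(B), "BP")
  expect_equal(s1, s2)
  expect_equal(fs_score(fx$dag, fx$annot, A, A)$fs, 1)
})

test_that("set-level FS matches a from-scratch re-evaluation", {
  fx <- study_fixture()
  dag <- fx$dag
  A <- fx$planted[1:5]
  B <- c(fx$planted[6:10], setdiff(annotated_genes(fx$annot),
                                   fx$planted)[1:5])
  for (ns in c("BP", "MF", "CC")) {
    terms_ns <- dag$terms[dag$namespace[dag$terms] == ns]
    edges <- do.call(rbind, lapply(terms_ns, function(t) {
      pr <- dag$parents[[t]]
      if (is.null(pr) || !nrow(pr)) return(NULL)
      data.frame(term = t, pr)
    }))
    gene_bma <- function(g1, g2) {
      t1 <- fx$annot[[ns]][[g1]]; t2 <- fx$annot[[ns]][[g2]]
      M <- outer(t1, t2, Vectorize(function(x, y)
        naive_wang(edges, dag$weights, x, y)))
      naive_bma(M)
    }
    a <- intersect(A, names(fx$annot[[ns]]))
    b <- intersect(B, names(fx$annot[[ns]]))
    M <- outer(a, b, Vectorize(gene_bma))
    expect_equal(gene_set_similarity(dag, fx$annot, A, B, ns),
                 naive_bma(M))
  }
})

test_that("FS screen counts its null and recovers planted annotations", {
  fx <- study_fixture()
  targets <- fx$library[["D002"]]          # planted drug
  res <- fs_screen(fx$dag, fx$annot, targets, fx$planted, n_perm = 100,
                   rng_seed = 9, drug_id = "D002")
  expect_equal(res$p, mean(res$null$samples > res$fs))
  expect_gt(res$fs, quantile(res$null$samples, 0.95))
  expect_equal(empirical_p(c(rep(1, 812), rep(0, 188)), 0.5, "greater"),
               0.812)
})

test_that("FS of a set against itself is 1 with the smallest attainable p", {
  fx <- study_fixture()
  res <- fs_screen(fx$dag, fx$annot, fx$planted, fx$planted, n_perm = 50,
                   rng_seed = 2)
  expect_equal(res$fs, 1)
  expect_equal(res$p, 0)
})

test_that("OBO files round-trip the DAG", {
  fx <- study_fixture()
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(fx$dag, path)
  dag2 <- read_obo(path)
  expect_setequal(dag2$terms, fx$dag$terms)
  expect_equal(dag2$namespace[sort(dag2$terms)],
               fx$dag$namespace[sort(fx$dag$terms)])
  edge_key <- function(d) {
    rows <- do.call(rbind, lapply(d$terms, function(t) {
      pr <- d$parents[[t]]
      if (is.null(pr) || !nrow(pr)) return(NULL)
      data.frame(term = t, pr)
    }))
    sort(paste(rows$term, rows$parent, rows$relation))
  }
  expect_identical(edge_key(dag2), edge_key(fx$dag))
})

test_that("GAF reading honours NOT qualifiers and the IEA flag", {
  dag <- hand_dag()
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("DB", "X1", "geneA", "", "a", "ref", "EXP", "", "P", sep = "\t"),
    paste("DB", "X2", "geneA", "NOT", "b", "ref", "EXP", "", "P", sep = "\t"),
    paste("DB", "X3", "geneB", "", "b", "ref", "IEA", "", "P", sep = "\t")),
    gaf)
  annot <- read_annotations(gaf, dag, format = "gaf")
  expect_equal(annot$BP[["geneA"]], "a")      # NOT row dropped
  expect_equal(annot$BP[["geneB"]], "b")      # IEA retained by default
  annot2 <- read_annotations(gaf, dag, format = "gaf", exclude_iea = TRUE)
  expect_null(annot2$BP[["geneB"]])
})
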