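#' Specification for a synthetic screening fixture
#'
#' Describes an artificial study system with known planted structure: a
#' scale-free interactome with a cohesive module around a seed gene, a drug
#' library whose drugs have graded target overlap with that module, a small
#' three-namespace ontology whose planted genes share a subtree of
#' annotations, and an expression matrix with planted tissue-specific genes.
#' Identical spec + seed reproduce identical fixtures.
#'
#' @param n_nodes interactome size (default 1000).
#' @param attachment edges per new node in the preferential-attachment
#'   background (default 3).
#' @param planted_module_size size of the planted cohesive gene set
#'   (default 25).
#' @param planted_density_boost multiple of the background edge density the
#'   planted set's induced subgraph must exceed (default 100; on a
#'   desk-scale network the module needs a density contrast strong enough to
#'   stand out against the hubs that absorb most propagation mass, the same
#'   cohesion-over-hubness contrast curated disease modules show at
#'   interactome scale).
#' @param n_drugs drugs in the library (default 50).
#' @param overlap_profile per-drug fraction of targets inside the planted
#'   module; default 3 fully-overlapping planted drugs and decoys at 0.
#' @param targets_per_drug targets per drug (default 6).
#' @param ontology_depth,ontology_branching tree depth (levels below the
#'   root) and branching factor per namespace (defaults 4, 3).
#' @param part_of_fraction fraction of ontology edges typed `part_of`
#'   (default 0.2).
#' @param terms_per_gene annotations per gene per namespace (default 3).
#' @param n_tissues tissues in the expression matrix (default 30).
#' @param expression_fold planted fold-change (linear scale) in the target
#'   tissue (default 8).
#' @param n_specific_genes planted tissue-specific genes (default 20).
#' @param master_seed integer seed driving every random choice (default 1).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_nodes = 1000, attachment = 3,
                         planted_module_size = 25,
                         planted_density_boost = 100,
                         n_drugs = 50,
                         overlap_profile = c(rep(1, 3), rep(0, n_drugs - 3)),
                         targets_per_drug = 6,
                         ontology_depth = 4, ontology_branching = 3,
                         part_of_fraction = 0.2, terms_per_gene = 3,
                         n_tissues = 30, expression_fold = 8,
                         n_specific_genes = 20, master_seed = 1) {
  stopifnot(planted_module_size < n_nodes,
            all(overlap_profile >= 0 & overlap_profile <= 1),
            length(overlap_profile) == n_drugs,
            ontology_depth >= 2, ontology_branching >= 2, n_tissues >= 2)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a scale-free interactome with a planted cohesive module
#'
#' Background graph by preferential attachment (heavy-tailed degrees, like a
#' real interactome); the planted members are drawn from the interquartile
#' degree range (disease modules are cohesive mid-degree neighborhoods, not
#' hub collections) and extra random edges are added inside the planted set
#' until its induced edge density exceeds the background density by the
#' configured multiple. The seed gene is the planted member with the most
#' within-module edges, so propagation from it ranks the planted set highly.
#'
#' @param spec a [fixture_spec()].
#' @return list: `graph` (interactome), `planted` (character vector),
#'   `seed_gene` (the most internally connected planted member).
#' @export
make_interactome <- function(spec) {
  with_seed(spec$master_seed, {
    g <- igraph::sample_pa(spec$n_nodes, power = 1, m = spec$attachment,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("G%04d", seq_len(spec$n_nodes))
    g <- igraph::simplify(g)
    deg <- igraph::degree(g)
    pool <- names(deg)[deg >= stats::quantile(deg, 0.25) &
                       deg <= stats::quantile(deg, 0.75)]
    planted <- sample(pool, spec$planted_module_size)
    n <- spec$n_nodes
    bg_density <- igraph::ecount(g) / (n * (n - 1) / 2)
    pairs <- t(utils::combn(planted, 2))
    need <- ceiling(spec$planted_density_boost * bg_density * nrow(pairs))
    if (need > nrow(pairs))
      stop("requested planted density is infeasible: need ", need,
           " edges among ", nrow(pairs), " pairs")
    have <- igraph::as_edgelist(
      igraph::induced_subgraph(g, planted))
    have_key <- paste(pmin(have[, 1], have[, 2]),
                      pmax(have[, 1], have[, 2]))
    pair_key <- paste(pmin(pairs[, 1], pairs[, 2]),
                      pmax(pairs[, 1], pairs[, 2]))
    free <- which(!pair_key %in% have_key)
    n_add <- max(0L, need - length(have_key))
    if (n_add > 0) {
      add <- pairs[sample(free, min(n_add, length(free))), , drop = FALSE]
      g <- igraph::add_edges(g, as.vector(t(add)))
    }
    internal_deg <- igraph::degree(igraph::induced_subgraph(g, planted))
    list(graph = g, planted = sort(planted),
         seed_gene = names(which.max(internal_deg)))
  })
}

#' Generate a drug library with graded module overlap and truth labels
#'
#' Each drug's targets are split per its overlap fraction: that share drawn
#' from the planted module, the rest degree-matched *outside* the module (so
#' decoys mimic the module's hubness without its cohesion). Truth label:
#' overlap >= 0.5.
#'
#' @param graph the fixture interactome.
#' @param planted the planted gene set.
#' @param spec a [fixture_spec()].
#' @return list: `library` (a `drug_target_library`), `truth` (data.frame
#'   drug, overlap, planted).
#' @export
make_drug_library <- function(graph, planted, spec) {
  bins <- degree_bins(graph)
  nodes <- igraph::V(graph)$name
  with_seed(spec$master_seed + 1L, {
    drugs <- sprintf("D%03d", seq_len(spec$n_drugs))
    lib <- vector("list", spec$n_drugs)
    names(lib) <- drugs
    for (i in seq_len(spec$n_drugs)) {
      k <- spec$targets_per_drug
      k_in <- round(spec$overlap_profile[i] * k)
      t_in <- if (k_in > 0) sample(planted, k_in) else character()
      t_out <- character()
      if (k - k_in > 0) {
        templates <- sample(planted, k - k_in, replace = TRUE)
        for (tpl in templates) {
          pool <- setdiff(bins$members[[as.character(bins$bin_of[[tpl]])]],
                          c(planted, t_out))
          if (!length(pool))
            stop("no degree-matched node left outside the planted module ",
                 "for template ", tpl)
          t_out <- c(t_out, sample(pool, 1))
        }
      }
      lib[[i]] <- sort(c(t_in, t_out))
    }
    truth <- data.frame(drug = drugs, overlap = spec$overlap_profile,
                        planted = spec$overlap_profile >= 0.5,
                        stringsAsFactors = FALSE)
    list(library = structure(lib, class = "drug_target_library",
                             n_filtered = 0L, affinity_threshold = Inf),
         truth = truth)
  })
}

# ids "T<NS>:<index>", a rooted tree per namespace
build_ns_tree <- function(ns, depth, branching, part_of_fraction) {
  ids <- sprintf("T%s:%04d", ns, 1L)
  parents <- data.frame(term = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  level_nodes <- list(ids)
  counter <- 1L
  for (d in seq_len(depth - 1L)) {
    new <- character()
    for (p in level_nodes[[d]]) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("T%s:%04d", ns, counter)
        rel <- if (stats::runif(1) < part_of_fraction) "part_of" else "is_a"
        parents <- rbind(parents, data.frame(
          term = id, parent = p, relation = rel, stringsAsFactors = FALSE))
        new <- c(new, id)
        ids <- c(ids, id)
      }
    }
    level_nodes[[d + 1L]] <- new
  }
  list(ids = ids, parents = parents, leaves = level_nodes[[depth]],
       root = level_nodes[[1L]][1L])
}

#' Generate a three-namespace ontology and gene annotations
#'
#' Builds disjoint rooted trees for BP, MF and CC of the configured depth
#' and branching (a configurable fraction of edges typed `part_of`). Planted
#' genes are co-annotated to leaves of a designated subtree (the first child
#' of each root); all other genes draw leaves from the remaining subtrees,
#' so planted genes are functionally coherent by construction.
#'
#' @param genes all gene symbols to annotate.
#' @param planted the planted gene set.
#' @param spec a [fixture_spec()].
#' @return list: `dag` (a `go_dag`), `annot` (an `annotation_map`).
#' @export
make_ontology_and_annotations <- function(genes, planted, spec) {
  with_seed(spec$master_seed + 2L, {
    trees <- lapply(c(BP = "BP", MF = "MF", CC = "CC"), function(ns)
      build_ns_tree(ns, spec$ontology_depth, spec$ontology_branching,
                    spec$part_of_fraction))
    ids <- unlist(lapply(trees, `[[`, "ids"), use.names = FALSE)
    nsv <- rep(c("BP", "MF", "CC"),
               vapply(trees, function(t) length(t$ids), 1L))
    parents <- do.call(rbind, lapply(trees, `[[`, "parents"))
    dag <- go_dag(ids, stats::setNames(nsv, ids), parents)
    gvec <- character(); tvec <- character()
    for (ns in c("BP", "MF", "CC")) {
      tr <- trees[[ns]]
      # leaves under the first child of the root form the designated subtree
      first_child <- tr$parents$term[tr$parents$parent == tr$root][1]
      sub_leaves <- tr$leaves[vapply(tr$leaves, function(l) {
        anc <- names(wang_s_values(dag, l))
        first_child %in% anc
      }, TRUE)]
      other_leaves <- setdiff(tr$leaves, sub_leaves)
      for (g in genes) {
        pool <- if (g %in% planted) sub_leaves else other_leaves
        gvec <- c(gvec, rep(g, spec$terms_per_gene))
        tvec <- c(tvec, sample(pool, spec$terms_per_gene,
                               replace = spec$terms_per_gene > length(pool)))
      }
    }
    list(dag = dag, annot = annotation_map(gvec, tvec, dag))
  })
}

#' Generate an expression matrix with planted tissue-specific genes
#'
#' Log-normal background: each gene has a baseline log2 level and
#' independent per-tissue noise; planted genes gain `log2(fold)` in the
#' first tissue. The matrix is on the log2 scale (recorded in its `scale`
#' attribute).
#'
#' @param genes gene symbols (rows).
#' @param spec a [fixture_spec()].
#' @return list: `matrix` (gene x tissue), `specific` (planted gene names),
#'   `tissue` (the boosted tissue label).
#' @export
make_expression <- function(genes, spec) {
  with_seed(spec$master_seed + 3L, {
    tissues <- sprintf("T%02d", seq_len(spec$n_tissues))
    base <- stats::rnorm(length(genes), mean = 5, sd = 1.5)
    m <- matrix(stats::rnorm(length(genes) * spec$n_tissues,
                             mean = rep(base, spec$n_tissues), sd = 0.5),
                nrow = length(genes), dimnames = list(genes, tissues))
    specific <- sample(genes, min(spec$n_specific_genes, length(genes)))
    m[specific, tissues[1]] <- m[specific, tissues[1]] +
      log2(spec$expression_fold)
    attr(m, "scale") <- "log2"
    list(matrix = m, specific = sort(specific), tissue = tissues[1])
  })
}

#' Write a DAG in OBO 1.2 format
#'
#' @param dag a `go_dag`.
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  long_ns <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", (dag$term_names %||% stats::setNames(dag$terms, dag$terms))[[t]] %||% t),
                 paste0("namespace: ", long_ns[[dag$namespace[[t]]]])), con)
    pr <- dag$parents[[t]]
    if (!is.null(pr) && nrow(pr)) {
      for (i in seq_len(nrow(pr))) {
        if (pr$relation[i] == "is_a")
          writeLines(paste0("is_a: ", pr$parent[i]), con)
        else
          writeLines(paste0("relationship: part_of ", pr$parent[i]), con)
      }
    }
  }
  invisible(path)
}

#' Write gene annotations as two-column TSV
#'
#' @param annot an `annotation_map`.
#' @param path output path.
#' @export
write_annotations <- function(annot, path) {
  rows <- do.call(rbind, lapply(c("BP", "MF", "CC"), function(ns) {
    a <- annot[[ns]]
    if (!length(a)) return(NULL)
    data.frame(gene = rep(names(a), lengths(a)),
               term = unlist(a, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$gene, rows$term), ]
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate and serialize a complete fixture
#'
#' Emits every fixture file in the package's external formats (edge-list
#' TSV, drug-target TSV, OBO, annotation TSV, expression TSV) plus truth
#' sidecars (planted genes, drug labels, tissue-specific genes) and a JSON
#' manifest.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return invisibly, the in-memory fixture (list with `graph`, `planted`,
#'   `seed_gene`, `library`, `truth`, `dag`, `annot`, `expression`).
#' @export
simulate_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_interactome(spec)
  dl <- make_drug_library(net$graph, net$planted, spec)
  onto <- make_ontology_and_annotations(igraph::V(net$graph)$name,
                                        net$planted, spec)
  expr <- make_expression(igraph::V(net$graph)$name, spec)
  write_edge_list(net$graph, file.path(dir, "interactome.tsv"))
  write_drug_library(dl$library, file.path(dir, "drug_targets.tsv"))
  write_obo(onto$dag, file.path(dir, "ontology.obo"))
  write_annotations(onto$annot, file.path(dir, "annotations.tsv"))
  write_expression(expr$matrix, file.path(dir, "expression.tsv"))
  writeLines(net$planted, file.path(dir, "planted_genes.txt"))
  write.table(dl$truth, file.path(dir, "drug_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(expr$specific, file.path(dir, "specific_genes.txt"))
  jsonlite::write_json(
    c(unclass(spec), list(seed_gene = net$seed_gene,
                          specific_tissue = expr$tissue)),
    file.path(dir, "fixture_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(graph = net$graph, planted = net$planted,
                 seed_gene = net$seed_gene, library = dl$library,
                 truth = dl$truth, dag = onto$dag, annot = onto$annot,
                 expression = expr))
}
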