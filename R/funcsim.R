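ns_map <- c(biological_process = "BP", molecular_function = "MF",
            cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC")

#' Construct a GO-style ontology DAG
#'
#' Holds child-to-parent typed links (`is_a`, `part_of`) across the three
#' disjoint namespaces (BP, MF, CC), with the semantic contribution weight of
#' each edge type used by Wang's similarity. Acyclicity is verified at
#' construction.
#'
#' @param terms character vector of term ids.
#' @param namespace named character vector (per term) with values in
#'   `c("BP","MF","CC")`.
#' @param parents data frame with columns `term`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @param weights named numeric contribution weights per edge type; Wang's
#'   published constants are the defaults.
#' @param names optional named character vector of term labels.
#' @return an object of class `go_dag`.
#' @export
go_dag <- function(terms, namespace, parents,
                   weights = c(is_a = 0.8, part_of = 0.6),
                   names = NULL) {
  terms <- unique(terms)
  stopifnot(all(names(namespace) %in% terms) || all(terms %in% names(namespace)))
  namespace <- namespace[terms]
  parents <- parents[parents$term %in% terms & parents$parent %in% terms, ]
  bad <- namespace[parents$term] != namespace[parents$parent]
  if (any(bad)) stop("ontology edge crosses namespaces: ",
                     parents$term[which(bad)[1]])
  # acyclicity via topological elimination
  g <- igraph::graph_from_data_frame(
    parents[, c("term", "parent")], directed = TRUE,
    vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) stop("ontology contains a cycle")
  parent_list <- split(
    data.frame(parent = parents$parent, relation = parents$relation,
               stringsAsFactors = FALSE),
    factor(parents$term, levels = terms))
  structure(list(terms = terms, namespace = namespace,
                 parents = parent_list, weights = weights,
                 term_names = names,
                 cache = new.env(parent = emptyenv())),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms (%s)\n", length(x$terms),
              paste(sprintf("%s=%d", names(table(x$namespace)),
                            table(x$namespace)), collapse = " ")))
  invisible(x)
}

#' Read an OBO 1.2 ontology
#'
#' Minimal reader for `[Term]` stanzas: `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`; obsolete terms are skipped, other relationship
#' types ignored.
#'
#' @param path OBO file path.
#' @param weights edge-type weights passed to [go_dag()].
#' @return a `go_dag`.
#' @export
read_obo <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
  lines <- readLines(path)
  idx <- which(lines == "[Term]")
  if (!length(idx)) stop("no [Term] stanza in ", path)
  bounds <- c(idx, length(lines) + 1L)
  ids <- character(); nss <- character(); nms <- character()
  edges <- list()
  for (i in seq_along(idx)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    block <- block[-1]
    block <- block[seq_len(max(0L, which(!nzchar(trimws(block)) |
                                         grepl("^\\[", block))[1] - 1L) %|na|%
                   length(block))]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v)) v else character()
    }
    if (length(get1("is_obsolete")) && any(get1("is_obsolete") == "true"))
      next
    id <- get1("id")[1]
    if (is.na(id) || !length(id)) next
    ns <- ns_map[get1("namespace")[1]]
    ids <- c(ids, id)
    nss <- c(nss, if (length(ns) && !is.na(ns)) ns else NA_character_)
    nm <- get1("name")
    nms <- c(nms, if (length(nm)) nm[1] else id)
    isa <- sub("\\s*!.*$", "", get1("is_a"))
    po <- grep("^part_of\\s", sub("\\s*!.*$", "", get1("relationship")),
               value = TRUE)
    po <- sub("^part_of\\s+", "", po)
    if (length(isa))
      edges[[length(edges) + 1L]] <- data.frame(
        term = id, parent = isa, relation = "is_a",
        stringsAsFactors = FALSE)
    if (length(po))
      edges[[length(edges) + 1L]] <- data.frame(
        term = id, parent = po, relation = "part_of",
        stringsAsFactors = FALSE)
  }
  parents <- if (length(edges)) do.call(rbind, edges)
             else data.frame(term = character(), parent = character(),
                             relation = character())
  go_dag(ids, stats::setNames(nss, ids), parents, weights = weights,
         names = stats::setNames(nms, ids))
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Read gene-to-term annotations
#'
#' Two formats: a two-column TSV (gene, term id) or GAF 2.x, where `NOT`-
#' qualified rows are dropped and IEA evidence retained by default. Terms
#' absent from the DAG are discarded with a count.
#'
#' @param path file path.
#' @param dag the [go_dag()] the annotations refer to.
#' @param format `"tsv"` or `"gaf"`.
#' @param exclude_iea drop IEA-evidence GAF rows (default FALSE).
#' @return an `annotation_map`: list with one `gene -> term set` list per
#'   namespace.
#' @export
read_annotations <- function(path, dag, format = c("tsv", "gaf"),
                             exclude_iea = FALSE) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    genes <- as.character(df[[1]]); terms <- as.character(df[[2]])
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^!", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(parts, length, 1L) >= 7
    parts <- parts[ok]
    qualifier <- vapply(parts, `[[`, "", 4L)
    evidence <- vapply(parts, `[[`, "", 7L)
    keep <- !grepl("NOT", qualifier)
    if (exclude_iea) keep <- keep & evidence != "IEA"
    genes <- vapply(parts, `[[`, "", 3L)[keep]
    terms <- vapply(parts, `[[`, "", 5L)[keep]
  }
  annotation_map(genes, terms, dag)
}

#' Build an annotation map from parallel gene/term vectors
#'
#' @param genes,terms parallel character vectors.
#' @param dag the [go_dag()]; unknown terms dropped (count in attribute
#'   `n_unknown_terms`).
#' @return an `annotation_map`.
#' @export
annotation_map <- function(genes, terms, dag) {
  known <- terms %in% dag$terms
  out <- lapply(c(BP = "BP", MF = "MF", CC = "CC"), function(ns) {
    sel <- known & dag$namespace[terms] == ns
    sel[is.na(sel)] <- FALSE
    lapply(split(terms[sel], genes[sel]), unique)
  })
  structure(out, class = "annotation_map",
            n_unknown_terms = sum(!known))
}

#' Genes annotated in at least one namespace
#' @param annot an `annotation_map`.
#' @return character vector of gene symbols.
#' @export
annotated_genes <- function(annot) {
  unique(unlist(lapply(annot, names), use.names = FALSE))
}

# Wang S-values of `term`: semantic contribution of each ancestor (and the
# term itself), S(t) = 1, S(a) = max over child edges of w_e * S(child).
wang_s_values <- function(dag, term) {
  key <- paste0("S\r", term)
  if (!is.null(dag$cache[[key]])) return(dag$cache[[key]])
  s <- stats::setNames(1, term)
  queue <- term
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    pr <- dag$parents[[t]]
    if (is.null(pr) || !nrow(pr)) next
    for (i in seq_len(nrow(pr))) {
      p <- pr$parent[i]
      w <- dag$weights[[pr$relation[i]]]
      cand <- w * s[[t]]
      if (is.na(s[p]) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  dag$cache[[key]] <- s
  s
}

#' Wang semantic similarity of two ontology terms
#'
#' DAG-topology similarity: each term's ancestor closure carries S-values
#' propagated downward-to-upward with edge-type weights; similarity is the
#' summed S-value mass on the shared ancestors relative to both terms' total
#' semantic value:
#' `sim = sum_{t in common}(S1(t) + S2(t)) / (SV1 + SV2)`.
#' Symmetric, in `[0, 1]`, and 1 exactly for identical terms.
#'
#' @param dag a [go_dag()].
#' @param t1,t2 term ids in the same namespace.
#' @return numeric similarity.
#' @export
wang_term_similarity <- function(dag, t1, t2) {
  for (t in c(t1, t2))
    if (!t %in% dag$terms) stop("unknown term: ", t)
  if (dag$namespace[[t1]] != dag$namespace[[t2]])
    stop("terms ", t1, " and ", t2, " are in different namespaces")
  M <- ns_sim_matrix(dag, dag$namespace[[t1]])
  if (!is.null(M)) return(M[t1, t2])
  key <- paste0("W\r", min(t1, t2), "\r", max(t1, t2))
  if (!is.null(dag$cache[[key]])) return(dag$cache[[key]])
  s1 <- wang_s_values(dag, t1)
  s2 <- wang_s_values(dag, t2)
  common <- intersect(names(s1), names(s2))
  v <- sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
  dag$cache[[key]] <- v
  v
}

# Dense term-by-term Wang similarity for one namespace, built once and
# cached. Worth its memory only for desk-scale ontologies; larger DAGs fall
# back to lazily cached pairwise evaluation (returns NULL).
ns_sim_matrix <- function(dag, ns, max_terms = 3000) {
  key <- paste0("M\r", ns)
  M <- dag$cache[[key]]
  if (!is.null(M)) return(if (is.matrix(M)) M else NULL)
  terms <- dag$terms[dag$namespace[dag$terms] == ns]
  if (length(terms) > max_terms || !length(terms)) {
    dag$cache[[key]] <- NA  # marker: do not build
    return(NULL)
  }
  sv <- lapply(terms, function(t) wang_s_values(dag, t))
  names(sv) <- terms
  tot <- vapply(sv, sum, 0)
  n <- length(terms)
  M <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    si <- sv[[i]]
    for (j in i:n) {
      common <- intersect(names(si), names(sv[[j]]))
      M[i, j] <- M[j, i] <-
        sum(si[common] + sv[[j]][common]) / (tot[[i]] + tot[[j]])
    }
  }
  dag$cache[[key]] <- M
  M
}

row_max <- function(M) apply(M, 1, max)

bma_aggregate <- function(M) {
  (mean(apply(M, 1, max)) + mean(apply(M, 2, max))) / 2
}

#' Best-match-average similarity of two genes in one namespace
#'
#' With annotation term sets T1 and T2 and the Wang pairwise matrix
#' `M[i, j]`, BMA averages the row-wise and column-wise maxima:
#' `(avg_i max_j M + avg_j max_i M) / 2`. A gene lacking annotation in the
#' namespace yields `NA` (missing, deliberately distinct from 0).
#'
#' @param dag a [go_dag()].
#' @param annot an `annotation_map`.
#' @param g1,g2 gene symbols.
#' @param ns namespace, one of `"BP"`, `"MF"`, `"CC"`.
#' @return similarity in `[0, 1]`, or `NA_real_`.
#' @export
bma_gene_similarity <- function(dag, annot, g1, g2, ns) {
  t1 <- annot[[ns]][[g1]]; t2 <- annot[[ns]][[g2]]
  if (is.null(t1) || is.null(t2)) return(NA_real_)
  S <- ns_sim_matrix(dag, ns)
  M <- if (!is.null(S)) S[t1, t2, drop = FALSE]
       else outer(t1, t2,
                  Vectorize(function(a, b) wang_term_similarity(dag, a, b)))
  bma_aggregate(M)
}

#' Set-versus-set functional similarity in one namespace
#'
#' BMA applied twice: Wang/BMA at the term level within each gene pair, then
#' BMA again over the gene-by-gene similarity matrix between the two sets.
#' Genes without annotation in the namespace are excluded (not zero-imputed).
#'
#' @param dag a [go_dag()].
#' @param annot an `annotation_map`.
#' @param set1,set2 character vectors of genes.
#' @param ns namespace.
#' @return similarity in `[0, 1]`, or `NA_real_` when either set has no
#'   annotated member.
#' @export
gene_set_similarity <- function(dag, annot, set1, set2, ns) {
  a1 <- intersect(unique(set1), names(annot[[ns]]))
  a2 <- intersect(unique(set2), names(annot[[ns]]))
  if (!length(a1) || !length(a2)) return(NA_real_)
  M <- matrix(0, length(a1), length(a2))
  for (i in seq_along(a1)) for (j in seq_along(a2))
    M[i, j] <- bma_gene_similarity(dag, annot, a1[i], a2[j], ns)
  bma_aggregate(M)
}

#' Functional-similarity score across the three GO namespaces
#'
#' Mean of the per-namespace set-vs-set similarities over namespaces where
#' both sets carry annotation (`FS = (Sim_BP + Sim_MF + Sim_CC)/3` when all
#' three are available).
#'
#' @inheritParams gene_set_similarity
#' @return list with `fs` and per-namespace `sim_bp`, `sim_mf`, `sim_cc`
#'   (`NA` where unavailable).
#' @export
fs_score <- function(dag, annot, set1, set2) {
  sims <- c(BP = gene_set_similarity(dag, annot, set1, set2, "BP"),
            MF = gene_set_similarity(dag, annot, set1, set2, "MF"),
            CC = gene_set_similarity(dag, annot, set1, set2, "CC"))
  if (all(is.na(sims)))
    stop("no namespace has annotated members in both sets")
  list(fs = mean(sims, na.rm = TRUE),
       sim_bp = sims[["BP"]], sim_mf = sims[["MF"]], sim_cc = sims[["CC"]])
}

#' Functional-similarity screen of one drug against the module
#'
#' Computes the three-namespace FS between the drug's targets and the module
#' genes, then a permutation null from random gene lists size-matched to the
#' drug's annotated target set, drawn uniformly from annotated genes (the
#' module side stays fixed). Reports the empirical
#' `P = #{FS_random > FS}/n_perm`. Annotation coverage, not degree, is the
#' confounder this null controls; `null_pool` lets callers supply a custom
#' pool (e.g. degree-matched candidates).
#'
#' @param dag a [go_dag()].
#' @param annot an `annotation_map`.
#' @param targets drug target gene symbols.
#' @param module a `gene_module` or character vector.
#' @param n_perm permutations (default 1000).
#' @param rng_seed master seed.
#' @param null_pool genes to draw null lists from (default: all annotated
#'   genes).
#' @param row_cache optional environment caching each candidate gene's
#'   similarity row against the module; share one across drugs when
#'   screening a whole library against a fixed module.
#' @param drug_id optional label.
#' @return object of class `fs_result`: `drug_id`, `fs`, `sim_bp`, `sim_mf`,
#'   `sim_cc`, `null`, `p`.
#' @export
fs_screen <- function(dag, annot, targets, module, n_perm = 1000,
                      rng_seed = NULL, null_pool = NULL, row_cache = NULL,
                      drug_id = NA_character_) {
  mod_genes <- if (inherits(module, "gene_module")) module$members else module
  pool <- null_pool %||% annotated_genes(annot)
  tg_ann <- intersect(unique(targets), annotated_genes(annot))
  if (!length(tg_ann))
    stop("no drug target carries any annotation")
  # the module side is fixed for the whole screen: cache each candidate
  # gene's BMA similarity against every annotated module gene per namespace
  mod_ann <- lapply(c(BP = "BP", MF = "MF", CC = "CC"), function(ns)
    intersect(unique(mod_genes), names(annot[[ns]])))
  if (is.null(row_cache)) row_cache <- new.env(parent = emptyenv())
  gene_row <- function(g, ns) {
    key <- paste0(ns, "\r", g)
    v <- row_cache[[key]]
    if (is.null(v)) {
      v <- vapply(mod_ann[[ns]], function(m)
        bma_gene_similarity(dag, annot, g, m, ns), 0)
      row_cache[[key]] <- v
    }
    v
  }
  set_fs <- function(genes) {
    sims <- vapply(c("BP", "MF", "CC"), function(ns) {
      a <- intersect(unique(genes), names(annot[[ns]]))
      if (!length(a) || !length(mod_ann[[ns]])) return(NA_real_)
      M <- do.call(rbind, lapply(a, gene_row, ns = ns))
      bma_aggregate(M)
    }, 0)
    mean(sims, na.rm = TRUE)
  }
  obs <- fs_score(dag, annot, targets, mod_genes)
  n_draw <- length(tg_ann)
  if (length(pool) < n_draw)
    stop("null pool smaller than the annotated target set")
  seeds <- spawn_seeds(rng_seed %||% sample.int(1e6, 1), n_perm)
  samples <- vapply(seeds, function(s) {
    rnd <- with_seed(s, sample(pool, n_draw))
    set_fs(rnd)
  }, 0)
  pn <- permutation_null(samples, seed = rng_seed %||% NA_integer_)
  structure(list(
    drug_id = drug_id, fs = obs$fs, sim_bp = obs$sim_bp,
    sim_mf = obs$sim_mf, sim_cc = obs$sim_cc, null = pn,
    p = empirical_p(samples, obs$fs, "greater")),
    class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("Functional similarity: %s FS=%.3f (BP=%.3f MF=%.3f CC=%.3f) P=%.4g\n",
              x$drug_id, x$fs, x$sim_bp, x$sim_mf, x$sim_cc, x$p))
  invisible(x)
}
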