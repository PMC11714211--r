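#' Column-normalized sparse transition matrix of an interactome
#'
#' `W[i, j] = a_ij / deg(j)`: the probability a walker at node j steps to
#' node i. Isolated nodes receive a unit self-loop column so W stays
#' column-stochastic.
#'
#' @param graph the interactome.
#' @return a `dgCMatrix` with node names as dimnames.
#' @keywords internal
transition_matrix <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  deg <- Matrix::colSums(A)
  iso <- which(deg == 0)
  if (length(iso)) {
    A[cbind(iso, iso)] <- 1
    deg[iso] <- 1
  }
  methods::as(A %*% Matrix::Diagonal(x = 1 / deg), "CsparseMatrix")
}

#' Personalized network propagation (personalized PageRank)
#'
#' Iterates `p <- damping * W p + (1 - damping) * v` to its fixed point,
#' where W is the column-normalized adjacency of the (undirected) interactome
#' and v the normalized personalization vector. With the restart mass
#' concentrated on a seed gene, the stationary scores measure each gene's
#' network influence from that seed; uniform v recovers ordinary PageRank.
#'
#' @param graph the interactome.
#' @param personalization named nonnegative vector of restart weights (names
#'   are node names; missing nodes get 0). Must have positive sum.
#' @param damping probability of following an edge rather than restarting
#'   (default 0.85).
#' @param tol L1 convergence threshold (default 1e-10).
#' @param max_iter iteration cap (default 1000); non-convergence warns and is
#'   flagged on the result.
#' @return named numeric vector over all nodes, nonnegative, summing to 1,
#'   with attributes `iterations` and `converged`.
#' @export
personalized_propagation <- function(graph, personalization,
                                     damping = 0.85, tol = 1e-10,
                                     max_iter = 1000) {
  stopifnot(damping > 0, damping < 1, tol > 0)
  nodes <- igraph::V(graph)$name
  v <- stats::setNames(numeric(length(nodes)), nodes)
  if (is.null(names(personalization)))
    stop("personalization must be a named vector")
  if (any(personalization < 0))
    stop("personalization weights must be nonnegative")
  known <- intersect(names(personalization), nodes)
  v[known] <- personalization[known]
  if (sum(v) <= 0)
    stop("personalization has zero total weight on graph nodes")
  v <- v / sum(v)
  W <- transition_matrix(graph)
  res <- .propagate_power(W@p, W@i, W@x, as.numeric(v), damping, tol,
                          as.integer(max_iter))
  if (!res$converged)
    warning("propagation did not converge in ", max_iter, " iterations")
  p <- res$p / sum(res$p)
  names(p) <- nodes
  attr(p, "iterations") <- res$iterations
  attr(p, "converged") <- res$converged
  p
}

#' Extract the top-k gene module from influence scores
#'
#' The module is the k genes with the highest propagation scores, the
#' seed-associated gene module used as reference set B by every screen.
#' Boundary ties break lexicographically by gene symbol so extraction is
#' deterministic. The seed gene(s) are excluded from membership by default
#' (the module is the seed's *associates*) but remain in the score map.
#'
#' @param scores named numeric vector from [personalized_propagation()].
#' @param k module size (default 200).
#' @param seed_genes character vector of seed gene(s), for exclusion and the
#'   record.
#' @param exclude_seed drop seed genes from membership (default TRUE).
#' @return object of class `gene_module`: `seed`, `scores`, `members`
#'   (descending score), `k`.
#' @export
extract_module <- function(scores, k = 200, seed_genes = character(),
                           exclude_seed = TRUE) {
  stopifnot(k >= 1)
  pool <- scores
  if (exclude_seed && length(seed_genes))
    pool <- pool[setdiff(names(pool), seed_genes)]
  if (k > length(pool)) {
    warning("k = ", k, " exceeds the ", length(pool),
            " scored genes; returning all")
    k <- length(pool)
  }
  ord <- order(-pool, names(pool))
  members <- names(pool)[ord][seq_len(k)]
  structure(list(seed = seed_genes, scores = scores,
                 members = members, k = k),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("Gene module: %d members (seed: %s)\n  top: %s ...\n",
              length(x$members),
              if (length(x$seed)) paste(x$seed, collapse = ",") else "none",
              paste(head(x$members, 5), collapse = ", ")))
  invisible(x)
}

#' Identify a seed-associated module in one call
#'
#' Runs [personalized_propagation()] with all restart mass on the seed
#' gene(s) and extracts the top-k module.
#'
#' @param graph the interactome.
#' @param seed_genes seed gene symbol(s); restart weight 1 on each.
#' @param k module size (default 200).
#' @param exclude_seed see [extract_module()].
#' @inheritParams personalized_propagation
#' @return a `gene_module`.
#' @export
identify_module <- function(graph, seed_genes, k = 200, damping = 0.85,
                            tol = 1e-10, max_iter = 1000,
                            exclude_seed = TRUE) {
  pers <- stats::setNames(rep(1, length(seed_genes)), seed_genes)
  scores <- personalized_propagation(graph, pers, damping, tol, max_iter)
  extract_module(scores, k = k, seed_genes = seed_genes,
                 exclude_seed = exclude_seed)
}

#' AUC of an influence-score ranking against a benchmark gene set
#'
#' Mann-Whitney formulation with ties averaged: the probability that a
#' random benchmark gene outranks a random non-benchmark gene. Used to
#' evaluate how well the module ranking recovers genes known to modulate the
#' phenotype.
#'
#' @param scores named numeric vector of influence scores.
#' @param benchmark character vector of positive genes; restricted to scored
#'   genes, must then be a nonempty proper subset.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_module_auc <- function(scores, benchmark) {
  pos <- names(scores) %in% benchmark
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0) stop("benchmark has no overlap with scored genes")
  if (n0 == 0) stop("benchmark covers all scored genes; AUC undefined")
  r <- rank(scores)           # ties averaged
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
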