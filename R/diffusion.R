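#' Random walk with restart over the interactome
#'
#' Iterates `p <- (1 - gamma) * W p + gamma * p0` to its stationary vector,
#' where W is the column-normalized adjacency and p0 spreads restart mass
#' uniformly over the seed nodes. The stationary probabilities score every
#' gene's network association with the seed set.
#'
#' The iteration also stops early when two successive vectors are
#' bit-identical (numerical stagnation), so arbitrarily small tolerances run
#' to the numerical fixed point rather than looping forever.
#'
#' @param graph the interactome.
#' @param seeds seed gene symbols (at least one in the graph).
#' @param gamma restart probability in (0, 1] (default 0.75, the customary
#'   diffusion-screen default).
#' @param tol L1 convergence threshold (default 1e-12).
#' @param max_iter iteration cap (default 10000); non-convergence warns.
#' @param W precomputed [transition_matrix()] of `graph`; pass it when
#'   running many walks on one graph to avoid rebuilding it.
#' @return named numeric vector over all nodes, nonnegative, summing to 1,
#'   with attributes `iterations` and `converged`.
#' @export
rwr <- function(graph, seeds, gamma = 0.75, tol = 1e-12, max_iter = 10000,
                W = NULL) {
  stopifnot(gamma > 0, gamma <= 1, tol > 0)
  nodes <- igraph::V(graph)$name
  sd_genes <- restrict_to_graph(graph, seeds, "seed set")
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[sd_genes] <- 1 / length(sd_genes)
  if (gamma == 1) {
    attr(p0, "iterations") <- 0L; attr(p0, "converged") <- TRUE
    return(p0)
  }
  if (is.null(W)) W <- transition_matrix(graph)
  res <- .propagate_power(W@p, W@i, W@x, as.numeric(p0), 1 - gamma, tol,
                          as.integer(max_iter))
  if (!res$converged)
    warning("RWR did not converge in ", max_iter, " iterations")
  p <- res$p
  names(p) <- nodes
  attr(p, "iterations") <- res$iterations
  attr(p, "converged") <- res$converged
  p
}

#' Diffusion-correlation screen of one drug against the module
#'
#' Runs RWR from the drug's targets, correlates (Pearson) the resulting
#' influence vector with the module's precomputed influence vector over all
#' graph nodes, and builds a permutation null by rerunning RWR from
#' degree-matched random target sets (the module vector is the screen's fixed
#' reference). Reports `z_rwr = (cor - mean)/sd` and the empirical
#' `P = #{cor_random > cor}/n_perm`.
#'
#' @param graph the interactome.
#' @param targets drug target gene symbols.
#' @param module_vector influence vector from [rwr()] seeded with the module.
#' @param n_perm permutations (default 1000).
#' @param rng_seed master seed.
#' @param gamma,tol,max_iter passed to [rwr()].
#' @param exclude_seeds drop target and module seed positions from the
#'   correlation (sensitivity analysis; default FALSE, correlate over all
#'   nodes).
#' @param module_seeds module seed genes, only needed when
#'   `exclude_seeds = TRUE`.
#' @param bins optional precomputed [degree_bins()].
#' @param W optional precomputed [transition_matrix()].
#' @param drug_id optional label.
#' @return object of class `rwr_result`: `drug_id`, `cor_obs`, `null`,
#'   `z_rwr`, `p`.
#' @export
rwr_screen <- function(graph, targets, module_vector, n_perm = 1000,
                       rng_seed = NULL, gamma = 0.75, tol = 1e-12,
                       max_iter = 10000, exclude_seeds = FALSE,
                       module_seeds = character(), bins = NULL, W = NULL,
                       drug_id = NA_character_) {
  tg <- restrict_to_graph(graph, targets, "target set")
  if (is.null(bins)) bins <- degree_bins(graph)
  if (is.null(W)) W <- transition_matrix(graph)
  nodes <- igraph::V(graph)$name
  mv <- as.numeric(module_vector[nodes])
  n <- length(nodes)
  # same iteration as rwr(), with the node alignment hoisted out of the
  # permutation loop
  walk <- function(members) {
    p0 <- numeric(n)
    p0[match(members, nodes)] <- 1 / length(members)
    if (gamma == 1) return(p0)
    .propagate_power(W@p, W@i, W@x, p0, 1 - gamma, tol,
                     as.integer(max_iter))$p
  }
  cor_with_module <- function(vec, seeds_used) {
    k <- rep(TRUE, n)
    if (exclude_seeds) k[match(c(seeds_used, module_seeds), nodes)] <- FALSE
    x <- vec[k]; y <- mv[k]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero-variance influence vector; correlation undefined")
    stats::cor(x, y)
  }
  cor_obs <- cor_with_module(walk(tg), tg)
  seeds <- spawn_seeds(rng_seed %||% sample.int(1e6, 1), n_perm)
  if (exclude_seeds) {
    samples <- vapply(seeds, function(s) {
      rnd <- sample_degree_matched(graph, tg, rng_seed = s, bins = bins)
      cor_with_module(walk(rnd), rnd)
    }, 0)
  } else {
    samples <- vapply(seeds, function(s) {
      rnd <- sample_degree_matched(graph, tg, rng_seed = s, bins = bins)
      stats::cor(walk(rnd), mv)
    }, 0)
  }
  pn <- permutation_null(samples, seed = rng_seed %||% NA_integer_)
  structure(list(
    drug_id = drug_id, cor_obs = cor_obs, null = pn,
    z_rwr = permutation_z(cor_obs, pn),
    p = empirical_p(samples, cor_obs, "greater")),
    class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf("RWR diffusion: %s cor=%.3f z_rwr=%.2f P=%.4g\n",
              x$drug_id, x$cor_obs, x$z_rwr, x$p))
  invisible(x)
}
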