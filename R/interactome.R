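#' Build an interactome graph from an edge data frame
#'
#' The interactome is an undirected, simple, labelled graph: self-loops are
#' dropped and duplicate edges (in either orientation) collapsed. All network
#' statistics in this package operate on such a graph.
#'
#' @param edges two-column data frame or matrix of gene symbols.
#' @return an [igraph::igraph] with vertex `name` attributes; attributes
#'   `n_self_loops` and `n_duplicates` record what was dropped.
#' @export
interactome <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge table needs two columns (gene A, gene B)")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  self <- a == b
  a <- a[!self]; b <- b[!self]
  # canonical orientation so (x,y) and (y,x) collapse
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup], stringsAsFactors = FALSE),
    directed = FALSE)
  attr(g, "n_self_loops") <- sum(self)
  attr(g, "n_duplicates") <- sum(dup)
  g
}

#' Read an interactome from a two-column TSV edge list
#'
#' Accepts an optional header row and `#` comment lines. Rows with a single
#' column are a parse error (reported with their line number); extra columns
#' are ignored.
#'
#' @param path file path.
#' @param header does the first non-comment row name the columns?
#' @return an undirected simple [igraph::igraph]; see [interactome()].
#' @export
load_edge_list <- function(path, header = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) { lines <- lines[-1]; lineno <- lineno[-1] }
  if (!length(lines)) stop("empty edge list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad))
    stop("malformed edge-list row (fewer than 2 columns) at line ",
         lineno[bad[1]], " of ", path)
  interactome(data.frame(
    from = vapply(parts, `[[`, "", 1L),
    to = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE))
}

#' Write an interactome as a TSV edge list
#'
#' @param graph the interactome.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets
#'
#' `read_gene_set()` reads one symbol per line (`#` comments allowed);
#' `read_gmt()`/`write_gmt()` handle the GMT format (set name, description,
#' then members, tab-separated).
#'
#' @param path file path.
#' @return a character vector, or for GMT a named list of character vectors.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  unique(lines[nzchar(lines)])
}

#' @rdname read_gene_set
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[[`, "", 1L))
}

#' @rdname read_gene_set
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

restrict_to_graph <- function(graph, genes, what = "gene set") {
  present <- intersect(unique(genes), igraph::V(graph)$name)
  if (!length(present)) stop(what, " has no member in the interactome")
  present
}

#' Minimum hop distance from a source set to every node
#'
#' Unweighted BFS distance from the nearest source; unreachable nodes get
#' `Inf`.
#'
#' @param graph the interactome.
#' @param sources character vector of source genes (at least one must be in
#'   the graph).
#' @return named numeric vector over all nodes.
#' @export
all_pairs_min_distance <- function(graph, sources) {
  src <- restrict_to_graph(graph, sources, "source set")
  d <- igraph::distances(graph, v = src, mode = "all")
  out <- apply(d, 2, min)
  stats::setNames(as.numeric(out), colnames(d))
}

#' Degree bins for degree-matched sampling
#'
#' Nodes are grouped by ascending degree, merging adjacent degree values
#' until every bin holds at least `min_size` nodes; the final bin absorbs any
#' remainder. This is the standard scheme for degree-preserving nulls on
#' heavy-tailed interactomes.
#'
#' @param graph the interactome.
#' @param min_size minimum nodes per bin (default 100).
#' @return object of class `degree_bins`: list with `bin_of` (named integer
#'   per node) and `members` (list of node-name vectors per bin).
#' @export
degree_bins <- function(graph, min_size = 100) {
  deg <- igraph::degree(graph)
  ord <- order(deg, names(deg))
  deg <- deg[ord]
  bin_of <- integer(length(deg)); names(bin_of) <- names(deg)
  bin <- 1L; count <- 0L; i <- 1L
  n <- length(deg)
  while (i <= n) {
    j <- i
    while (j < n && deg[j + 1L] == deg[i]) j <- j + 1L  # whole degree value
    bin_of[i:j] <- bin
    count <- count + (j - i + 1L)
    if (count >= min_size) { bin <- bin + 1L; count <- 0L }
    i <- j + 1L
  }
  # a trailing undersized bin is merged back into its predecessor
  if (count > 0L && count < min_size && bin > 1L)
    bin_of[bin_of == bin] <- bin - 1L
  structure(list(bin_of = bin_of,
                 members = split(names(bin_of), bin_of)),
            class = "degree_bins")
}

#' Sample a degree-matched random gene set
#'
#' Draws `length(template)` distinct nodes, one from the degree bin of each
#' template node, without replacement within the draw. Controls for hub bias
#' in all permutation nulls of this package.
#'
#' @param graph the interactome.
#' @param template character vector of node names to match (must all be in
#'   the graph).
#' @param rng_seed integer seed for a reproducible draw, or `NULL`.
#' @param bins precomputed [degree_bins()] (recomputed if `NULL`).
#' @param min_bin_size passed to [degree_bins()] when `bins` is `NULL`.
#' @return character vector of node names, same length as `template`.
#' @export
sample_degree_matched <- function(graph, template, rng_seed = NULL,
                                  bins = NULL, min_bin_size = 100) {
  if (is.null(bins)) bins <- degree_bins(graph, min_bin_size)
  tb <- bins$bin_of[template]
  if (anyNA(tb))
    stop("template node(s) not in graph: ",
         paste(head(template[is.na(tb)], 3), collapse = ", "))
  ub <- unique(tb)
  with_seed(rng_seed, {
    out <- lapply(ub, function(b) {
      pool <- bins$members[[as.character(b)]]
      k <- sum(tb == b)
      if (length(pool) < k)
        stop("degree bin ", b, " holds ", length(pool), " nodes but ", k,
             " are required; rebuild bins with a larger min_size ",
             "(coarser binning)")
      pool[sample.int(length(pool), k)]
    })
    unlist(out, use.names = FALSE)
  })
}

#' Size of the largest connected component induced by a gene set
#'
#' @param graph the interactome.
#' @param genes character vector of genes.
#' @return integer LCC size (0 if no gene is in the graph).
#' @export
lcc_size <- function(graph, genes) {
  present <- intersect(unique(genes), igraph::V(graph)$name)
  if (!length(present)) return(0L)
  sub <- igraph::induced_subgraph(graph, present)
  max(igraph::components(sub)$csize)
}

#' Localization test of a gene set's largest connected component
#'
#' Tests whether a gene set induces a larger connected subgraph than expected
#' for random sets of the same size — the classic evidence that a putative
#' disease module is topologically coherent. The null preserves the set's
#' degree distribution by default (uniform sampling available).
#'
#' @param graph the interactome.
#' @param genes character vector (at least 2 members must be in the graph).
#' @param n_perm number of random sets (default 1000).
#' @param rng_seed master seed.
#' @param null `"degree_matched"` (default) or `"uniform"`.
#' @param bins optional precomputed [degree_bins()].
#' @return object of class `lcc_result`: `observed_lcc`, `null`
#'   ([permutation_null()]), `z` (`NA` if the null is degenerate), and
#'   `empirical_p` = fraction of null samples >= observed.
#' @export
lcc_significance <- function(graph, genes, n_perm = 1000, rng_seed = NULL,
                             null = c("degree_matched", "uniform"),
                             bins = NULL) {
  null <- match.arg(null)
  present <- intersect(unique(genes), igraph::V(graph)$name)
  if (length(present) < 2)
    stop("need at least 2 genes present in the graph")
  obs <- lcc_size(graph, present)
  if (null == "degree_matched" && is.null(bins)) bins <- degree_bins(graph)
  seeds <- spawn_seeds(rng_seed %||% sample.int(1e6, 1), n_perm)
  samples <- vapply(seeds, function(s) {
    rand <- if (null == "degree_matched")
      sample_degree_matched(graph, present, rng_seed = s, bins = bins)
    else with_seed(s, sample(igraph::V(graph)$name, length(present)))
    as.numeric(lcc_size(graph, rand))
  }, 0)
  pn <- permutation_null(samples, seed = rng_seed %||% NA_integer_)
  structure(list(observed_lcc = obs, null = pn,
                 z = permutation_z(obs, pn),
                 empirical_p = empirical_p(samples, obs, "geq")),
            class = "lcc_result")
}

#' @export
print.lcc_result <- function(x, ...) {
  cat(sprintf("LCC localization: observed=%d null mean=%.2f sd=%.2f z=%.2f P=%.4g\n",
              x$observed_lcc, x$null$mean, x$null$sd,
              x$z %||% NA_real_, x$empirical_p))
  invisible(x)
}
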