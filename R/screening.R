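#' Load a drug-target library from TSV
#'
#' Columns: drug id, target gene symbol, optional binding affinity (µM).
#' When the affinity column is present, rows above the threshold are dropped
#' (the standard "physical binder" filter at 10 µM); duplicates collapse.
#'
#' @param path file path; `#` comments and an optional header allowed.
#' @param affinity_threshold keep rows with affinity <= this (µM; default
#'   10). Ignored without an affinity column.
#' @param header does the file carry a header row?
#' @return object of class `drug_target_library`: named list `drug ->
#'   character vector of targets`, with attributes `n_filtered` (rows dropped
#'   by the affinity filter) and `affinity_threshold`.
#' @export
load_drug_library <- function(path, affinity_threshold = 10, header = FALSE) {
  df <- read.delim(path, header = header, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty drug-target library: ", path)
  drug_target_library(df, affinity_threshold = affinity_threshold)
}

#' Build a drug-target library from a data frame
#'
#' @param df data frame: drug id, target, optional affinity.
#' @param affinity_threshold see [load_drug_library()].
#' @return a `drug_target_library`.
#' @export
drug_target_library <- function(df, affinity_threshold = 10) {
  drug <- as.character(df[[1]]); target <- as.character(df[[2]])
  n_filtered <- 0L
  if (ncol(df) >= 3) {
    aff <- suppressWarnings(as.numeric(df[[3]]))
    keep <- !is.na(aff) & aff <= affinity_threshold
    n_filtered <- sum(!keep)
    drug <- drug[keep]; target <- target[keep]
  }
  if (!length(drug)) stop("drug-target library is empty after filtering")
  lib <- lapply(split(target, drug), unique)
  structure(lib, class = "drug_target_library",
            n_filtered = n_filtered,
            affinity_threshold = affinity_threshold)
}

#' Write a drug-target library as two-column TSV
#' @param library a `drug_target_library`.
#' @param path output path.
#' @export
write_drug_library <- function(library, path) {
  df <- data.frame(
    drug = rep(names(library), lengths(library)),
    target = unlist(library, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.drug_target_library <- function(x, ...) {
  cat(sprintf("Drug-target library: %d drugs, %d interactions (%d rows affinity-filtered)\n",
              length(x), sum(lengths(x)), attr(x, "n_filtered")))
  invisible(x)
}

#' Screen thresholds for candidate calls
#'
#' The printed operating points of the three methods: proximal when
#' `z_np < -3` and `P < 0.05`; functionally similar when `FS > 0.6` and
#' `P < 0.05`; diffusion-associated when `z_rwr > 3` and `P < 0.05`. A final
#' candidate must pass all three.
#'
#' @param z_np,p_np,fs,p_fs,z_rwr,p_rwr the six cutoffs.
#' @return named list of thresholds.
#' @export
screen_thresholds <- function(z_np = -3, p_np = 0.05, fs = 0.6,
                              p_fs = 0.05, z_rwr = 3, p_rwr = 0.05) {
  list(z_np = z_np, p_np = p_np, fs = fs, p_fs = p_fs,
       z_rwr = z_rwr, p_rwr = p_rwr)
}

#' Run the full three-method drug screen
#'
#' For every drug in the library: closest-proximity screen, functional-
#' similarity screen (skipped with a recorded reason when no ontology is
#' supplied), and RWR diffusion screen against the module's influence
#' vector. Per-drug permutation seeds derive from `(rng_seed, drug id)`, so
#' adding or removing drugs never perturbs other drugs' nulls, and the whole
#' report is reproducible bit-for-bit from the master seed. Per-drug failures
#' (e.g. no target in the graph) are recorded as skip reasons, never abort
#' the screen.
#'
#' @param graph the interactome.
#' @param module a `gene_module`.
#' @param library a `drug_target_library`.
#' @param dag,annot optional [go_dag()] + `annotation_map` enabling the FS
#'   method.
#' @param n_perm permutations per method per drug (default 1000).
#' @param rng_seed master seed (default 1).
#' @param gamma RWR restart probability.
#' @param thresholds a [screen_thresholds()] list.
#' @param module_rwr_seeds seeds of the module-side RWR: `"module"`
#'   (default, the module members) or `"seed_gene"` (the module's seed gene
#'   only).
#' @param randomize_np passed to [proximity_screen()] (`"both"` or
#'   `"targets"`).
#' @return object of class `screen_report`: `report` (one data.frame row per
#'   drug), `results` (per-drug method objects), `params`.
#' @export
run_screen <- function(graph, module, library, dag = NULL, annot = NULL,
                       n_perm = 1000, rng_seed = 1, gamma = 0.75,
                       thresholds = screen_thresholds(),
                       module_rwr_seeds = c("module", "seed_gene"),
                       randomize_np = "both") {
  module_rwr_seeds <- match.arg(module_rwr_seeds)
  stopifnot(inherits(module, "gene_module"),
            inherits(library, "drug_target_library"))
  bins <- degree_bins(graph)
  W <- transition_matrix(graph)
  rwr_seed_genes <- if (module_rwr_seeds == "module") module$members
                    else module$seed
  module_vec <- rwr(graph, rwr_seed_genes, gamma = gamma, W = W)
  D <- if (igraph::vcount(graph) <= 4000) distance_matrix(graph)
  do_fs <- !is.null(dag) && !is.null(annot)
  ann_pool <- if (do_fs) annotated_genes(annot)
  fs_cache <- if (do_fs) new.env(parent = emptyenv())
  drugs <- names(library)
  rows <- vector("list", length(drugs))
  results <- vector("list", length(drugs))
  names(results) <- drugs
  for (i in seq_along(drugs)) {
    id <- drugs[i]
    targets <- library[[id]]
    tg <- intersect(targets, igraph::V(graph)$name)
    row <- data.frame(
      drug = id, n_targets = length(targets), n_targets_in_graph = length(tg),
      d = NA_real_, z_np = NA_real_, p_np = NA_real_, pass_np = NA,
      fs = NA_real_, p_fs = NA_real_, pass_fs = NA,
      cor = NA_real_, z_rwr = NA_real_, p_rwr = NA_real_, pass_rwr = NA,
      final_candidate = NA, skip_reason = "", stringsAsFactors = FALSE)
    if (!length(tg)) {
      row$skip_reason <- "no target in interactome"
      rows[[i]] <- row
      next
    }
    res <- list()
    np <- tryCatch(
      proximity_screen(graph, tg, module, n_perm = n_perm,
                       rng_seed = derive_seed(rng_seed, paste0("np:", id)),
                       randomize = randomize_np, bins = bins, D = D,
                       drug_id = id),
      error = function(e) conditionMessage(e))
    if (is.character(np)) {
      row$skip_reason <- paste0("NP: ", np)
    } else {
      res$np <- np
      row$d <- np$d_obs; row$z_np <- np$z_np; row$p_np <- np$p
      row$pass_np <- !is.na(np$z_np) && np$z_np < thresholds$z_np &&
        np$p < thresholds$p_np
    }
    if (do_fs) {
      fsr <- tryCatch(
        fs_screen(dag, annot, targets, module, n_perm = n_perm,
                  rng_seed = derive_seed(rng_seed, paste0("fs:", id)),
                  null_pool = ann_pool, row_cache = fs_cache,
                  drug_id = id),
        error = function(e) conditionMessage(e))
      if (is.character(fsr)) {
        row$skip_reason <- paste(row$skip_reason, paste0("FS: ", fsr))
      } else {
        res$fs <- fsr
        row$fs <- fsr$fs; row$p_fs <- fsr$p
        row$pass_fs <- fsr$fs > thresholds$fs & fsr$p < thresholds$p_fs
      }
    } else {
      row$skip_reason <- paste(row$skip_reason, "FS: no ontology supplied")
    }
    rw <- tryCatch(
      rwr_screen(graph, tg, module_vec, n_perm = n_perm,
                 rng_seed = derive_seed(rng_seed, paste0("rwr:", id)),
                 gamma = gamma, bins = bins, W = W, drug_id = id),
      error = function(e) conditionMessage(e))
    if (is.character(rw)) {
      row$skip_reason <- paste(row$skip_reason, paste0("RWR: ", rw))
    } else {
      res$rwr <- rw
      row$cor <- rw$cor_obs; row$z_rwr <- rw$z_rwr; row$p_rwr <- rw$p
      row$pass_rwr <- !is.na(rw$z_rwr) && rw$z_rwr > thresholds$z_rwr &&
        rw$p < thresholds$p_rwr
    }
    row$skip_reason <- trimws(row$skip_reason)
    pass <- c(row$pass_np, if (do_fs) row$pass_fs, row$pass_rwr)
    row$final_candidate <- if (anyNA(pass)) NA else all(pass)
    rows[[i]] <- row
    results[[i]] <- res
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, results = results,
                 params = list(n_perm = n_perm, rng_seed = rng_seed,
                               gamma = gamma, thresholds = thresholds,
                               module_rwr_seeds = module_rwr_seeds,
                               randomize_np = randomize_np,
                               k = length(module$members),
                               seed_genes = module$seed)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cs <- candidate_sets(x)
  cat(sprintf("Screen report: %d drugs | NP %d, FS %d, RWR %d, intersection %d\n",
              nrow(x$report), length(cs$np), length(cs$fs), length(cs$rwr),
              length(cs$all_three)))
  invisible(x)
}

#' Candidate sets and their intersections from a screen report
#'
#' Exposes the per-method candidate sets and every pairwise intersection as
#' well as the three-way intersection, so judgment calls beyond the
#' all-three rule (e.g. advancing drugs supported by two methods plus
#' literature) remain the user's decision.
#'
#' @param x a `screen_report`.
#' @return named list of character vectors: `np`, `fs`, `rwr`, `np_fs`,
#'   `np_rwr`, `fs_rwr`, `all_three`.
#' @export
candidate_sets <- function(x) {
  r <- x$report
  np <- r$drug[r$pass_np %in% TRUE]
  fs <- r$drug[r$pass_fs %in% TRUE]
  rw <- r$drug[r$pass_rwr %in% TRUE]
  list(np = np, fs = fs, rwr = rw,
       np_fs = intersect(np, fs), np_rwr = intersect(np, rw),
       fs_rwr = intersect(fs, rw),
       all_three = Reduce(intersect, list(np, fs, rw)))
}

#' Write a screen report and run manifest
#'
#' Writes the combined per-drug table as TSV and a JSON manifest of all
#' parameters and seeds. Identical inputs and master seed produce
#' byte-identical files.
#'
#' @param x a `screen_report`.
#' @param dir output directory (created if absent).
#' @return the report TSV path, invisibly.
#' @export
write_screen_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "screen_report.tsv")
  df <- x$report
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$params, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
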