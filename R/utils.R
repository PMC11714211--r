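#' @importFrom stats cor sd rnorm setNames
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp evalCpp
#' @importFrom methods as
#' @useDynLib netrepurpose, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `code`, and restores the
#' previous state on exit, so library calls never perturb a caller's stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream as-is.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Spawn reproducible child seeds from a master seed
#'
#' One master seed drives a whole permutation ensemble: each permutation (or
#' each drug in a screen) gets its own child seed so results are reproducible
#' and insensitive to evaluation order.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Derive a per-drug seed from a master seed and a drug identifier
#'
#' Hashes the drug id into the seed so that adding or removing drugs from a
#' library never perturbs the permutation null of any other drug.
#'
#' @param master integer master seed.
#' @param id character identifier (e.g. a drug id).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 31 + b) %% 2147483629
  as.integer((as.numeric(master) %% 2147483629 * 65537 + h) %% 2147483629) + 1L
}

#' Construct a permutation-null summary
#'
#' @param samples numeric vector of the statistic under randomization.
#' @param seed the seed that produced the samples (for the record).
#' @return an object of class `permutation_null` with fields `samples`,
#'   `n_perm`, `mean`, `sd`, `seed`.
#' @export
permutation_null <- function(samples, seed = NA_integer_) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  structure(
    list(samples = samples, n_perm = length(samples),
         mean = mean(samples), sd = stats::sd(samples), seed = seed),
    class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("Permutation null: n_perm=%d mean=%.4g sd=%.4g\n",
              x$n_perm, x$mean, x$sd))
  invisible(x)
}

#' Permutation Z-score
#'
#' `(observed - mean(null)) / sd(null)`; returns `NA` when the null has zero
#' spread (the undefined-Z sentinel), leaving the empirical P interpretable.
#'
#' @param observed observed statistic.
#' @param null a [permutation_null()].
#' @return numeric Z or `NA_real_`.
#' @export
permutation_z <- function(observed, null) {
  if (!inherits(null, "permutation_null")) null <- permutation_null(null)
  if (is.na(null$sd) || null$sd == 0) return(NA_real_)
  (observed - null$mean) / null$sd
}

#' Empirical P from permutation samples
#'
#' Counting fraction exactly as the screen formulas print it, with no +1
#' smoothing, so P = 0 is reportable:
#' * `"less"`:    P = #\{sample < observed\} / n  (proximity screen),
#' * `"greater"`: P = #\{sample > observed\} / n  (functional-similarity and
#'   diffusion screens),
#' * `"geq"`:     P = #\{sample >= observed\} / n  (LCC localization),
#' * `"leq"`:     P = #\{sample <= observed\} / n  (proximal-tail variant).
#'
#' @param samples numeric null samples.
#' @param observed observed statistic.
#' @param comparison which tail count to take.
#' @return a proportion in `[0, 1]`.
#' @export
empirical_p <- function(samples, observed,
                        comparison = c("less", "greater", "geq", "leq")) {
  comparison <- match.arg(comparison)
  if (inherits(samples, "permutation_null")) samples <- samples$samples
  switch(comparison,
    less    = mean(samples < observed),
    greater = mean(samples > observed),
    geq     = mean(samples >= observed),
    leq     = mean(samples <= observed))
}
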