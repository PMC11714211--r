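#' Read a gene-by-tissue expression matrix
#'
#' TSV with genes as rows, tissues as columns, a header row of tissue labels
#' and gene symbols in the first column. Values are per-tissue mean
#' expression; the scale (log or linear) is the caller's choice and is only
#' recorded, never transformed.
#'
#' @param path file path.
#' @param scale free-text scale label recorded as attribute `scale`.
#' @return numeric matrix with gene rownames and tissue colnames.
#' @export
load_expression <- function(path, scale = "unspecified") {
  df <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (ncol(m) < 2) stop("expression matrix needs at least 2 tissues")
  if (anyNA(m)) stop("expression matrix contains missing values")
  storage.mode(m) <- "double"
  attr(m, "scale") <- scale
  m
}

#' Write an expression matrix as TSV
#' @param matrix gene-by-tissue matrix.
#' @param path output path.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tissue-specificity Z-score per gene
#'
#' `Z[i, t] = (E(i, t) - mean_i) / sd_i`, centring each gene's expression in
#' the target tissue on its cross-tissue mean and scaling by its cross-tissue
#' standard deviation. Genes with zero spread get `NA` (undefined, not 0).
#'
#' @param matrix gene-by-tissue matrix of mean expression.
#' @param tissue target tissue label (a column name).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator, under which each gene's Z values sum to 0 across
#'   tissues).
#' @return named numeric vector of Z-scores per gene.
#' @export
tissue_z <- function(matrix, tissue, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!tissue %in% colnames(matrix))
    stop("unknown tissue: ", tissue)
  mu <- rowMeans(matrix)
  dev <- matrix - mu
  n <- ncol(matrix)
  ss <- rowSums(dev^2)
  sdev <- sqrt(ss / if (sd_type == "sample") n - 1 else n)
  z <- (matrix[, tissue] - mu) / sdev
  z[sdev == 0] <- NA_real_
  z
}

#' Genes exceeding a tissue-specificity threshold
#'
#' Strict inequality `Z > threshold`; the customary operating point for
#' calling a gene tissue-specific is 2.5.
#'
#' @param z named Z-score vector from [tissue_z()].
#' @param threshold cutoff (default 2.5).
#' @return character vector of gene symbols (genes with undefined Z never
#'   qualify).
#' @export
specific_genes <- function(z, threshold = 2.5) {
  names(z)[!is.na(z) & z > threshold]
}
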