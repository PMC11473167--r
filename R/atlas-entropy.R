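#' Construct a tissue expression atlas
#'
#' A tissue atlas is a non-negative genes x tissues expression matrix in
#' arbitrary linear units (e.g. normalized microarray intensities of a
#' multi-tissue expression catalog). It is the substrate for entropy-based
#' tissue-specificity scoring.
#'
#' @param values numeric matrix, genes in rows, tissues in columns;
#'   non-negative, no missing values.
#' @param gene_ids,tissue_ids unique identifiers; default to the dimnames of
#'   `values`.
#' @return a `tissue_atlas` object (a classed numeric matrix).
#' @seealso [classify_tras()], [entropy_score()]
#' @export
tissue_atlas <- function(values, gene_ids = rownames(values),
                         tissue_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("atlas values must be numeric", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("atlas values must be non-negative with no missing entries",
         call. = FALSE)
  }
  if (ncol(values) < 2) {
    stop("a tissue atlas needs at least 2 tissues", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(tissue_ids)) {
    stop("gene and tissue identifiers are required", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(tissue_ids)) stop("duplicate tissue ids", call. = FALSE)
  dimnames(values) <- list(as.character(gene_ids), as.character(tissue_ids))
  class(values) <- c("tissue_atlas", "matrix", "array")
  values
}

#' @export
print.tissue_atlas <- function(x, ...) {
  cat(sprintf("tissue_atlas: %d genes x %d tissues\n", nrow(x), ncol(x)))
  invisible(x)
}

# Shannon entropy of a non-negative abundance vector; NA for an all-zero
# vector (undefined, never a number). Zero entries contribute nothing.
shannon_entropy <- function(x, base) {
  tot <- sum(x)
  if (tot == 0) {
    return(NA_real_)
  }
  p <- x[x > 0] / tot
  -sum(p * log(p)) / log(base)
}

#' Shannon entropy tissue-specificity score
#'
#' Scores how broadly a gene is expressed across tissues:
#' \eqn{H = -\sum_t p_t \log_2 p_t} with \eqn{p_t = x_t / \sum_u x_u}.
#' A gene expressed in a single tissue scores 0 bits; a gene expressed
#' uniformly over \eqn{T} tissues scores \eqn{\log_2 T} bits. Low entropy
#' therefore flags tissue-restricted expression.
#'
#' @param x non-negative expression vector over tissues (length >= 2).
#' @param base logarithm base; 2 (bits, the default) matches the
#'   tissue-restriction threshold of 3.0 bits.
#' @return entropy in `base` units, or `NA` for an all-zero vector
#'   (entropy undefined; such genes are excluded from classification).
#' @examples
#' entropy_score(rep(1, 8))      # 3 bits, uniform over 8 tissues
#' entropy_score(c(5, 0, 0, 0))  # 0 bits, single-tissue
#' @export
entropy_score <- function(x, base = 2) {
  x <- as.numeric(x)
  if (length(x) < 2) {
    stop("expression vector must cover at least 2 tissues", call. = FALSE)
  }
  if (anyNA(x)) stop("missing expression values", call. = FALSE)
  if (any(x < 0)) stop("negative expression values", call. = FALSE)
  shannon_entropy(x, base = base)
}

#' Classify tissue-restricted antigen (TRA) genes in an atlas
#'
#' Computes the entropy score of every gene and calls a gene a TRA when its
#' score falls strictly below `threshold` (default 3.0 bits, i.e. expression
#' support effectively narrower than 8 tissues). Genes with zero total
#' expression have undefined entropy; they are excluded from the TRA
#' universe and reported in the `"excluded"` attribute.
#'
#' @param atlas a [tissue_atlas()] (or genes x tissues matrix).
#' @param threshold entropy threshold in `base` units; strict `<`.
#' @param base logarithm base for the entropy score.
#' @return data frame with one row per gene: `gene_id`, `entropy`,
#'   `total_expression`, `is_tra` (`NA` for zero-total genes). Attribute
#'   `excluded` carries the ids of zero-total genes.
#' @export
classify_tras <- function(atlas, threshold = 3, base = 2) {
  atlas <- tissue_atlas(unclass(atlas))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("entropy threshold must be a single positive number", call. = FALSE)
  }
  tot <- rowSums(atlas)
  p <- atlas / ifelse(tot > 0, tot, 1)
  terms <- ifelse(p > 0, p * log(p), 0)
  h <- -rowSums(terms) / log(base)
  h[tot == 0] <- NA_real_
  res <- data.frame(
    gene_id = rownames(atlas),
    entropy = h,
    total_expression = tot,
    is_tra = ifelse(is.na(h), NA, h < threshold),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(res, "excluded") <- rownames(atlas)[tot == 0]
  attr(res, "threshold") <- threshold
  res
}

#' Extract the TRA gene set from a classification
#'
#' @param classification result of [classify_tras()].
#' @return character vector of TRA gene ids.
#' @export
tra_genes <- function(classification) {
  classification$gene_id[!is.na(classification$is_tra) & classification$is_tra]
}
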