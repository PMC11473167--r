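#' Shannon-Weaver diversity index
#'
#' \eqn{H' = -\sum_i p_i \ln p_i} over abundance proportions
#' \eqn{p_i = x_i / \sum_j x_j}; zero abundances contribute nothing. Natural
#' log by default, the convention of community-ecology software; the base is
#' exposed for callers that want bits.
#'
#' @param x non-negative abundance vector (here: expression of TRA genes in
#'   one sample).
#' @param base logarithm base (default `exp(1)`).
#' @return H' in `base` units, or `NA` for an all-zero vector.
#' @examples
#' shannon_weaver(rep(1, 10))  # ln 10
#' @export
shannon_weaver <- function(x, base = exp(1)) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0)) {
    stop("abundances must be non-negative and complete", call. = FALSE)
  }
  shannon_entropy(x, base = base)
}

#' Per-sample diversity of the expressed TRA repertoire
#'
#' @param expr an `expression_table` from [rpkm()] (or an RPKM matrix).
#' @param tra TRA gene ids over which diversity is evaluated.
#' @param base logarithm base for [shannon_weaver()].
#' @return data frame with `sample_id`, `H_prime`, `n_tra_expressed`.
#' @export
tra_diversity <- function(expr, tra, base = exp(1)) {
  mat <- if (inherits(expr, "expression_table")) expr$rpkm else as.matrix(expr)
  tra <- intersect(tra, rownames(mat))
  if (!length(tra)) stop("no TRA genes found in the expression table",
                         call. = FALSE)
  sub <- mat[tra, , drop = FALSE]
  data.frame(
    sample_id = colnames(sub),
    H_prime = apply(sub, 2, shannon_weaver, base = base),
    n_tra_expressed = colSums(sub > 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compare per-sample diversity across genotypes
#'
#' One-way ANOVA of H' on genotype followed by Dunnett many-to-one
#' comparisons of each knockout against the control (multivariate-t
#' adjustment via multcomp). The Dunnett quantile is evaluated with a
#' locally pinned RNG state so reports stay bit-reproducible.
#'
#' @param diversity data frame from [tra_diversity()].
#' @param design a [sample_design()] data frame.
#' @param control genotype used as the comparison baseline.
#' @return list with `anova` (`F`, `p`), `comparisons` (data frame with
#'   `genotype`, `estimate`, `p_adj`) and `method`.
#' @export
diversity_compare <- function(diversity, design, control = "control") {
  d <- merge(diversity, design, by = "sample_id")
  d$genotype <- droplevels(factor(d$genotype))
  if (nlevels(d$genotype) < 2) {
    stop("need at least 2 genotype groups", call. = FALSE)
  }
  if (any(table(d$genotype) < 2)) {
    stop("need at least 2 samples per genotype", call. = FALSE)
  }
  d$genotype <- stats::relevel(d$genotype, ref = control)
  fit <- stats::aov(H_prime ~ genotype, data = d)
  an <- summary(fit)[[1]]
  dn <- with_local_seed(1, {
    summary(multcomp::glht(fit,
                           linfct = multcomp::mcp(genotype = "Dunnett")))
  })
  comparisons <- data.frame(
    genotype = sub(" - .*$", "", names(dn$test$coefficients)),
    estimate = unname(dn$test$coefficients),
    p_adj = unname(as.numeric(dn$test$pvalues)),
    stringsAsFactors = FALSE
  )
  list(
    anova = list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1]),
    comparisons = comparisons,
    method = "dunnett"
  )
}

#' Pearson correlation with a two-tailed p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite values.
#' @return list with `r`, `p`, `n`; `r = NA` when either vector has zero
#'   variance.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  n <- length(x)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- sum(dx * dy) / (sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg step-up q-values
#'
#' \eqn{q_i = \min_{j \ge rank(i)} p_{(j)} m / j}, capped at 1; the output
#' preserves the input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @examples
#' bh_fdr(c(0.005, 0.1))
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Paired per-gene retention comparisons by category
#'
#' For every TRA dependence class and knockout genotype, compares the
#' per-gene intron ratios of the knockout against the control, paired over
#' genes (Wilcoxon signed-rank by default, paired t as option), and adjusts
#' the family of p-values with [bh_fdr()]. Genes must have a defined ratio
#' (total reads > 0) in both genotypes; classes with fewer than `min_genes`
#' such genes are flagged untestable.
#'
#' @param counts a [feature_counts()] object.
#' @param design a [sample_design()] data frame.
#' @param categories a [categorize_tras()] table.
#' @param genotypes knockout genotypes to compare against `control`.
#' @param method `"wilcoxon"` (signed-rank, default) or `"t"` (paired t).
#' @param min_genes minimum testable genes per class.
#' @return data frame with one row per class x genotype: `category`,
#'   `genotype`, `n_genes`, `mean_control`, `mean_ko`, `p_value`, `q_value`,
#'   `untestable`.
#' @export
category_retention_tests <- function(counts, design, categories,
                                     genotypes = c("prmt5_ko", "aire_ko"),
                                     method = c("wilcoxon", "t"),
                                     min_genes = 3) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "feature_counts"))
  idx_control <- intron_retention_index(counts, design, "control")
  classes <- c("TRA_Prmt5", "TRA_Aire", "TRA_shared", "TRA_other")
  rows <- list()
  for (g in genotypes) {
    idx_ko <- intron_retention_index(counts, design, g)
    for (cl in classes) {
      genes <- categories$gene_id[categories$category == cl]
      genes <- genes[genes %in% names(idx_ko)]
      ok <- genes[!is.na(idx_ko[genes]) & !is.na(idx_control[genes]) &
                    counts$intronic_length[genes] > 0]
      untestable <- length(ok) < min_genes
      p <- NA_real_
      if (!untestable) {
        xk <- idx_ko[ok]
        xc <- idx_control[ok]
        p <- if (all(xk == xc)) {
          1
        } else if (method == "wilcoxon") {
          suppressWarnings(
            stats::wilcox.test(xk, xc, paired = TRUE, exact = FALSE)$p.value
          )
        } else {
          stats::t.test(xk, xc, paired = TRUE)$p.value
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        category = cl, genotype = g, n_genes = length(ok),
        mean_control = if (length(ok)) mean(idx_control[ok]) else NA_real_,
        mean_ko = if (length(ok)) mean(idx_ko[ok]) else NA_real_,
        p_value = p, untestable = untestable, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  testable <- !out$untestable & !is.na(out$p_value)
  if (any(testable)) out$q_value[testable] <- bh_fdr(out$p_value[testable])
  out
}
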