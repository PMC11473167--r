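#' Genes expressed in a reference group
#'
#' A gene counts as expressed when its mean RPKM over the samples of
#' `group` is strictly positive.
#'
#' @param expr an `expression_table` from [rpkm()] (or an RPKM matrix).
#' @param design a [sample_design()] data frame.
#' @param group genotype defining the reference compartment.
#' @return character vector of expressed gene ids.
#' @export
expressed_filter <- function(expr, design, group = "control") {
  mat <- if (inherits(expr, "expression_table")) expr$rpkm else as.matrix(expr)
  samples <- design$sample_id[design$genotype == group]
  if (!length(samples)) {
    stop(sprintf("no samples with genotype '%s'", group), call. = FALSE)
  }
  m <- rowMeans(mat[, samples, drop = FALSE])
  rownames(mat)[m > 0]
}

#' Per-gene differential expression between a knockout and control
#'
#' Tests every gene with an unpaired, equal-variance (Student's) two-tailed
#' t test on `log2(RPKM + epsilon)`, and computes the linear fold change
#' `mean(KO) / mean(control)` (with the same epsilon guard when the control
#' mean is zero). A gene is flagged `down` when `p < p_threshold` and
#' `fold_change < fc_down`, and `up` when `p < p_threshold` and
#' `fold_change > fc_up`; all inequalities are strict. A gene that is
#' constant and identical in both groups cannot be tested and is flagged
#' `untestable` with `p = NA`.
#'
#' @param expr an `expression_table` from [rpkm()] (or an RPKM matrix).
#' @param design a [sample_design()] data frame.
#' @param contrast character pair `c(ko, control)`.
#' @param p_threshold,fc_down,fc_up flag thresholds.
#' @param epsilon pseudocount on the log scale and zero-denominator guard.
#' @param scale `"log2"` (default) tests on `log2(RPKM + epsilon)`;
#'   `"linear"` tests the raw RPKM values.
#' @return data frame keyed by `gene_id` with group means, `fold_change`,
#'   `t`, `p_value`, and logical `down`, `up`, `untestable`.
#' @export
diff_test <- function(expr, design, contrast = c("prmt5_ko", "control"),
                      p_threshold = 0.05, fc_down = 0.5, fc_up = 2,
                      epsilon = 0.01, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  mat <- if (inherits(expr, "expression_table")) expr$rpkm else as.matrix(expr)
  ko_s <- design$sample_id[design$genotype == contrast[1]]
  ct_s <- design$sample_id[design$genotype == contrast[2]]
  if (length(ko_s) < 2 || length(ct_s) < 2) {
    stop("need at least 2 replicates on each side of the contrast",
         call. = FALSE)
  }
  ko <- mat[, ko_s, drop = FALSE]
  ct <- mat[, ct_s, drop = FALSE]
  tk <- if (scale == "log2") log2(ko + epsilon) else ko
  tc <- if (scale == "log2") log2(ct + epsilon) else ct

  n1 <- ncol(tk)
  n2 <- ncol(tc)
  m1 <- rowMeans(tk)
  m2 <- rowMeans(tc)
  v1 <- apply(tk, 1, stats::var)
  v2 <- apply(tc, 1, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  untestable <- sp2 == 0 & m1 == m2
  p[sp2 == 0 & m1 != m2] <- 0
  tstat[sp2 == 0 & m1 != m2] <- Inf * sign((m1 - m2)[sp2 == 0 & m1 != m2])
  p[untestable] <- NA_real_
  tstat[untestable] <- NA_real_

  mean_ko <- rowMeans(ko)
  mean_ct <- rowMeans(ct)
  fc <- ifelse(mean_ct > 0, mean_ko / mean_ct,
               (mean_ko + epsilon) / (mean_ct + epsilon))
  down <- !is.na(p) & p < p_threshold & fc < fc_down
  up <- !is.na(p) & p < p_threshold & fc > fc_up

  data.frame(
    gene_id = rownames(mat),
    mean_control = mean_ct, mean_ko = mean_ko,
    fold_change = fc, t = tstat, p_value = p,
    down = down, up = up, untestable = untestable,
    row.names = rownames(mat), stringsAsFactors = FALSE
  )
}

tra_category_levels <- function() {
  c("TRA_Prmt5", "TRA_Aire", "TRA_shared", "TRA_other",
    "non_TRA", "not_expressed")
}

#' Categorize expressed TRA genes by regulator dependence
#'
#' Partitions the gene universe: genes not expressed in the control
#' compartment are `not_expressed`; expressed non-TRA genes are `non_TRA`;
#' expressed TRA genes split by their `down` flags in the two knockout
#' contrasts into `TRA_Prmt5` (down only in the Prmt5 knockout), `TRA_Aire`
#' (down only in the Aire knockout), `TRA_shared` (down in both) and
#' `TRA_other` (down in neither).
#'
#' @param tra gene ids classified as TRA (see [tra_genes()]).
#' @param diff_prmt5,diff_aire [diff_test()] results for the two contrasts;
#'   must cover the same gene universe.
#' @param expressed gene ids passing [expressed_filter()].
#' @param universe optional full gene universe; defaults to the genes of
#'   `diff_prmt5`.
#' @return data frame with `gene_id` and `category` (factor over the six
#'   classes).
#' @export
categorize_tras <- function(tra, diff_prmt5, diff_aire, expressed,
                            universe = diff_prmt5$gene_id) {
  if (!setequal(diff_prmt5$gene_id, diff_aire$gene_id)) {
    stop("the two contrasts must cover the same gene universe",
         call. = FALSE)
  }
  missing <- setdiff(universe, diff_prmt5$gene_id)
  if (length(missing)) {
    stop("gene(s) missing from a contrast: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  dp <- diff_prmt5$down[match(universe, diff_prmt5$gene_id)]
  da <- diff_aire$down[match(universe, diff_aire$gene_id)]
  is_expr <- universe %in% expressed
  is_tra <- universe %in% tra
  category <- ifelse(
    !is_expr, "not_expressed",
    ifelse(!is_tra, "non_TRA",
           ifelse(dp & da, "TRA_shared",
                  ifelse(dp, "TRA_Prmt5",
                         ifelse(da, "TRA_Aire", "TRA_other"))))
  )
  data.frame(
    gene_id = universe,
    category = factor(category, levels = tra_category_levels()),
    stringsAsFactors = FALSE
  )
}

#' Summarize TRA category counts
#'
#' Reports the count and percentage (to one decimal, half away from zero)
#' of each TRA dependence class among expressed TRA genes, plus the share of
#' Prmt5-dependent TRAs (`TRA_Prmt5` plus `TRA_shared`) that are also
#' Aire-dependent (`TRA_shared` over that union).
#'
#' @param x a [categorize_tras()] table, or a numeric vector of four class
#'   counts in the order Prmt5-only, Aire-only, shared, other.
#' @return list with `total` (expressed TRA genes), `counts`, `percent`,
#'   and `prmt5_dependent_aire_share` (percent, or `NA` when no
#'   Prmt5-dependent TRA exists).
#' @examples
#' summarize_categories(c(168, 576, 651, 1471))
#' @export
summarize_categories <- function(x) {
  classes <- c("TRA_Prmt5", "TRA_Aire", "TRA_shared", "TRA_other")
  if (is.data.frame(x)) {
    counts <- table(factor(x$category, levels = classes))
    counts <- stats::setNames(as.integer(counts), classes)
  } else {
    if (length(x) != 4 || any(x < 0)) {
      stop("expected four non-negative class counts", call. = FALSE)
    }
    counts <- stats::setNames(as.integer(x), classes)
  }
  total <- sum(counts)
  if (total == 0) {
    return(list(total = 0L, counts = counts,
                percent = stats::setNames(rep(NA_real_, 4), classes),
                prmt5_dependent_aire_share = NA_real_))
  }
  percent <- round_half_up(100 * counts / total, 1)
  prmt5_dep <- counts["TRA_Prmt5"] + counts["TRA_shared"]
  share <- if (prmt5_dep > 0) {
    round_half_up(100 * counts[["TRA_shared"]] / prmt5_dep, 1)
  } else {
    NA_real_
  }
  list(total = total, counts = counts, percent = percent,
       prmt5_dependent_aire_share = unname(share))
}
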