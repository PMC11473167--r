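#' Per-gene intron retention index of a genotype group
#'
#' The intron retention index of a gene is the ratio of intron reads to
#' total (exon plus intron) reads. Replicates of the group are aggregated
#' as a ratio of pooled sums by default, which is robust for low-count
#' genes; `aggregation = "mean"` instead averages per-sample ratios. Genes
#' with zero total reads in the group (or, in `"mean"` mode, in every
#' sample) get `NA`.
#'
#' @param counts a [feature_counts()] object.
#' @param design a [sample_design()] data frame.
#' @param group genotype whose samples are aggregated.
#' @param aggregation `"pooled"` (ratio of sums) or `"mean"` (mean of
#'   per-sample ratios).
#' @return named numeric vector of per-gene ratios in `[0, 1]` (or `NA`).
#' @export
intron_retention_index <- function(counts, design, group,
                                   aggregation = c("pooled", "mean")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(counts, "feature_counts"))
  if (!group %in% design$genotype) {
    stop(sprintf("unknown genotype '%s'", group), call. = FALSE)
  }
  samples <- design$sample_id[design$genotype == group]
  ex <- counts$exon[, samples, drop = FALSE]
  intr <- counts$intron[, samples, drop = FALSE]
  if (aggregation == "pooled") {
    tot <- rowSums(ex) + rowSums(intr)
    ratio <- ifelse(tot > 0, rowSums(intr) / tot, NA_real_)
  } else {
    tot <- ex + intr
    per <- ifelse(tot > 0, intr / tot, NA)
    ratio <- rowMeans(per, na.rm = TRUE)
    ratio[rowSums(tot) == 0] <- NA_real_
  }
  stats::setNames(ratio, rownames(counts$exon))
}

#' Filter genes on a minimum group read count
#'
#' @param counts a [feature_counts()] object.
#' @param design a [sample_design()] data frame.
#' @param group genotype whose pooled total (exon plus intron) is tested.
#' @param threshold inclusive minimum total read count (default 10).
#' @return character vector of gene ids with group total `>= threshold`.
#' @export
min_read_filter <- function(counts, design, group, threshold = 10) {
  stopifnot(inherits(counts, "feature_counts"))
  samples <- design$sample_id[design$genotype == group]
  if (!length(samples)) {
    stop(sprintf("unknown genotype '%s'", group), call. = FALSE)
  }
  tot <- rowSums(counts$exon[, samples, drop = FALSE]) +
    rowSums(counts$intron[, samples, drop = FALSE])
  rownames(counts$exon)[tot >= threshold]
}

#' Retention fold change between knockout and control
#'
#' `retention_fc = (index_ko + epsilon) / (index_control + epsilon)`; the
#' small epsilon keeps genes with a zero index finite. Genes are flagged
#' `increased` when the fold change is strictly above `up` (default 1.5)
#' and `decreased` when strictly below `down` (default 0.75).
#'
#' @param index_ko,index_control named per-gene ratios from
#'   [intron_retention_index()]; matched by name.
#' @param epsilon additive guard on both ratios.
#' @param up,down flag thresholds.
#' @return data frame with `gene_id`, `index_ko`, `index_control`,
#'   `retention_fc`, `increased`, `decreased` (both `NA` when either index
#'   is undefined).
#' @export
retention_fold_change <- function(index_ko, index_control, epsilon = 1e-3,
                                  up = 1.5, down = 0.75) {
  genes <- intersect(names(index_ko), names(index_control))
  if (!length(genes)) stop("no shared genes", call. = FALSE)
  ik <- index_ko[genes]
  ic <- index_control[genes]
  fc <- (ik + epsilon) / (ic + epsilon)
  data.frame(
    gene_id = genes, index_ko = unname(ik), index_control = unname(ic),
    retention_fc = unname(fc),
    increased = unname(fc > up), decreased = unname(fc < down),
    row.names = genes, stringsAsFactors = FALSE
  )
}

#' Per-category intron-ratio distributions and top-k retention panel
#'
#' For every TRA dependence class, collects the per-gene intron ratios in
#' each genotype (single-exon genes, which have no introns, are excluded and
#' reported), their class means, and the panel of the `top_n` genes from
#' `panel_category` ranked by retention fold change in the given contrast —
#' the data behind the retention heatmaps.
#'
#' @param counts a [feature_counts()] object.
#' @param design a [sample_design()] data frame.
#' @param categories a [categorize_tras()] table.
#' @param contrast character pair `c(ko, control)` for the panel ranking.
#' @param panel_category class from which the top panel is drawn.
#' @param top_n panel size.
#' @param min_reads inclusive minimum pooled read count in the knockout for
#'   panel membership.
#' @param epsilon guard passed to [retention_fold_change()].
#' @return list with `ratios` (per-class list of gene x genotype matrices),
#'   `means` (class x genotype matrix), `top_panel` (ranked data frame) and
#'   `excluded_intronless` (gene ids without introns).
#' @export
category_retention_table <- function(counts, design, categories,
                                     contrast = c("prmt5_ko", "control"),
                                     panel_category = "TRA_Prmt5",
                                     top_n = 30, min_reads = 10,
                                     epsilon = 1e-3) {
  stopifnot(inherits(counts, "feature_counts"))
  genos <- levels(design$genotype)
  idx <- sapply(genos, function(g) {
    intron_retention_index(counts, design, g)
  })
  intronless <- rownames(counts$exon)[counts$intronic_length == 0]

  classes <- c("TRA_Prmt5", "TRA_Aire", "TRA_shared", "TRA_other")
  ratios <- list()
  means <- matrix(NA_real_, length(classes), length(genos),
                  dimnames = list(classes, genos))
  for (cl in classes) {
    genes <- setdiff(categories$gene_id[categories$category == cl],
                     intronless)
    if (!length(genes)) {
      warning(sprintf("category %s is empty", cl), call. = FALSE)
      ratios[[cl]] <- idx[character(0), , drop = FALSE]
      next
    }
    ratios[[cl]] <- idx[genes, , drop = FALSE]
    means[cl, ] <- colMeans(ratios[[cl]], na.rm = TRUE)
  }

  panel_genes <- setdiff(
    categories$gene_id[categories$category == panel_category], intronless
  )
  panel_genes <- intersect(
    panel_genes, min_read_filter(counts, design, contrast[1], min_reads)
  )
  top_panel <- if (length(panel_genes)) {
    fc <- retention_fold_change(idx[panel_genes, contrast[1]],
                                idx[panel_genes, contrast[2]],
                                epsilon = epsilon)
    fc <- fc[order(-fc$retention_fc, fc$gene_id), , drop = FALSE]
    utils::head(fc, top_n)
  } else {
    warning("empty top panel", call. = FALSE)
    NULL
  }
  list(ratios = ratios, means = means, top_panel = top_panel,
       excluded_intronless = intronless)
}
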