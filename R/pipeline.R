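#' Configuration of the end-to-end pipeline
#'
#' Collects the stage thresholds (all defaulting to the analysis' standard
#' operating values), the input mode, and the seed. Exactly one input mode
#' is active: `input = NULL` simulates a dataset from `params`; otherwise
#' `input` must name files for `atlas`, `counts` and `design` written by
#' [write_atlas()], [write_counts()] and [write_design()].
#'
#' @param params a [simulation_params()] object (simulation mode).
#' @param input optional list of file paths (`atlas`, `counts`, `design`).
#' @param entropy_threshold TRA entropy cut-off in bits (strict `<`).
#' @param p_threshold,fc_down,fc_up differential-expression flag thresholds.
#' @param retention_up,retention_down retention fold-change flag thresholds.
#' @param min_reads inclusive minimum knockout read count for retention
#'   analysis.
#' @param q_threshold FDR level used when reporting category comparisons.
#' @param epsilon pseudocount for [diff_test()].
#' @param retention_epsilon guard for [retention_fold_change()].
#' @param seed integer seed overriding `params$seed` when given.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(params = simulation_params(), input = NULL,
                            entropy_threshold = 3, p_threshold = 0.05,
                            fc_down = 0.5, fc_up = 2, retention_up = 1.5,
                            retention_down = 0.75, min_reads = 10,
                            q_threshold = 0.05, epsilon = 0.01,
                            retention_epsilon = 1e-3, seed = NULL) {
  thresholds <- c(entropy_threshold = entropy_threshold,
                  p_threshold = p_threshold, fc_down = fc_down,
                  fc_up = fc_up, retention_up = retention_up,
                  retention_down = retention_down, min_reads = min_reads,
                  q_threshold = q_threshold, epsilon = epsilon,
                  retention_epsilon = retention_epsilon)
  if (any(thresholds <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  if (!is.null(input) &&
      !all(c("atlas", "counts", "design") %in% names(input))) {
    stop("file input needs atlas, counts and design paths", call. = FALSE)
  }
  if (!is.null(seed)) params$seed <- as.integer(seed)
  structure(
    list(params = params, input = input, thresholds = as.list(thresholds),
         seed = params$seed),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: a `params` block of
#' [simulation_params()] fields, an optional `input` block of file paths,
#' and top-level threshold overrides.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(simulation_params, y$params %||% list())
  args <- y[setdiff(names(y), c("params", "input"))]
  do.call(pipeline_config,
          c(list(params = params, input = y$input), args))
}

map_truth_category <- function(category) {
  c(tra_prmt5 = "TRA_Prmt5", tra_aire = "TRA_Aire",
    tra_shared = "TRA_shared", tra_other = "TRA_other",
    non_tra = "non_TRA", silent = "not_expressed")[category]
}

# Truth-based evaluation of a simulated run: category recovery, retention
# flag sensitivity/specificity on the planted splicing-deficient set.
recovery_metrics <- function(categories, retention_fc, truth,
                             contrast_ko = "prmt5_ko") {
  pred <- categories$category[match(truth$gene_id, categories$gene_id)]
  expected <- map_truth_category(truth$category)
  tra_classes <- c("TRA_Prmt5", "TRA_Aire", "TRA_shared", "TRA_other")
  recalls <- vapply(tra_classes, function(cl) {
    in_class <- expected == cl
    if (!any(in_class)) return(NA_real_)
    mean(pred[in_class] == cl, na.rm = TRUE)
  }, numeric(1))
  balanced_accuracy <- mean(recalls, na.rm = TRUE)

  deficient <- truth$category %in% affected_genotypes()[[contrast_ko]] &
    truth$spliceable
  other <- truth$category == "tra_other" & truth$spliceable
  flagged <- retention_fc$gene_id[!is.na(retention_fc$increased) &
                                    retention_fc$increased]
  tested <- retention_fc$gene_id
  def_tested <- truth$gene_id[deficient][truth$gene_id[deficient] %in% tested]
  oth_tested <- truth$gene_id[other][truth$gene_id[other] %in% tested]
  list(
    balanced_accuracy = balanced_accuracy,
    class_recall = recalls,
    retention_sensitivity = if (length(def_tested)) {
      mean(def_tested %in% flagged)
    } else {
      NA_real_
    },
    retention_false_flag_rate = if (length(oth_tested)) {
      mean(oth_tested %in% flagged)
    } else {
      NA_real_
    }
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain — simulate (or load) inputs, classify TRA genes
#' on the atlas, compute RPKM, filter expressed genes, test both knockout
#' contrasts, categorize TRAs, quantify intron retention, and compute
#' diversity and association statistics — and returns a machine-readable
#' run report. Identical configuration and seed give a bit-identical
#' report. When `out_dir` is given, all intermediate tables (TSV) and the
#' report (JSON) are persisted there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a `run_report` list; in simulation mode it carries the full
#'   stage results in attribute `"state"` (truth, counts, tables) for
#'   programmatic consumers.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  simulate_mode <- is.null(config$input)

  if (simulate_mode) {
    ds <- simulate_dataset(config$params)
    atlas <- ds$atlas
    counts <- ds$counts
    design <- ds$design
    truth <- ds$truth
  } else {
    atlas <- read_atlas(config$input$atlas)
    counts <- read_counts(config$input$counts)
    design <- read_design(config$input$design)
    truth <- NULL
  }

  classification <- classify_tras(atlas, threshold = th$entropy_threshold)
  tra <- tra_genes(classification)
  expr <- rpkm(counts)
  expressed <- expressed_filter(expr, design, group = "control")

  diff_prmt5 <- diff_test(expr, design, c("prmt5_ko", "control"),
                          p_threshold = th$p_threshold,
                          fc_down = th$fc_down, fc_up = th$fc_up,
                          epsilon = th$epsilon)
  diff_aire <- diff_test(expr, design, c("aire_ko", "control"),
                         p_threshold = th$p_threshold,
                         fc_down = th$fc_down, fc_up = th$fc_up,
                         epsilon = th$epsilon)
  categories <- categorize_tras(tra, diff_prmt5, diff_aire, expressed)
  cat_summary <- summarize_categories(
    categories[categories$category %in%
                 c("TRA_Prmt5", "TRA_Aire", "TRA_shared", "TRA_other"), ]
  )

  idx_control <- intron_retention_index(counts, design, "control")
  idx_prmt5 <- intron_retention_index(counts, design, "prmt5_ko")
  keep <- min_read_filter(counts, design, "prmt5_ko",
                          threshold = th$min_reads)
  keep <- keep[counts$intronic_length[keep] > 0]
  ret_fc <- retention_fold_change(idx_prmt5[keep], idx_control[keep],
                                  epsilon = th$retention_epsilon,
                                  up = th$retention_up,
                                  down = th$retention_down)
  ret_table <- suppressWarnings(
    category_retention_table(counts, design, categories,
                             min_reads = th$min_reads,
                             epsilon = th$retention_epsilon)
  )
  cat_tests <- category_retention_tests(counts, design, categories)

  diversity <- tra_diversity(expr, tra)
  div_comp <- diversity_compare(diversity, design)

  # inverse coupling: retention change vs expression change over TRA genes
  corr_genes <- intersect(intersect(tra, expressed), ret_fc$gene_id)
  correlation <- if (length(corr_genes) >= 3) {
    x <- log2(ret_fc[corr_genes, "retention_fc"])
    y <- log2(pmax(diff_prmt5[corr_genes, "fold_change"], 1e-6))
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3) c(pearson_cor(x[ok], y[ok]),
                        list(n_genes = sum(ok))) else NULL
  } else {
    NULL
  }

  report <- list(
    package = "trasplice",
    version = as.character(utils::packageVersion("trasplice")),
    seed = config$seed,
    mode = if (simulate_mode) "simulate" else "files",
    thresholds = th,
    stages = list(
      n_genes = nrow(counts$exon),
      n_samples = ncol(counts$exon),
      n_atlas_genes = nrow(atlas),
      n_tra = length(tra),
      n_zero_atlas = length(attr(classification, "excluded")),
      n_expressed = length(expressed),
      n_down_prmt5 = sum(diff_prmt5$down),
      n_down_aire = sum(diff_aire$down),
      n_retention_tested = nrow(ret_fc),
      n_retention_increased = sum(ret_fc$increased, na.rm = TRUE),
      n_retention_decreased = sum(ret_fc$decreased, na.rm = TRUE),
      n_intronless_excluded = length(ret_table$excluded_intronless)
    ),
    category_summary = list(
      total = cat_summary$total,
      counts = as.list(cat_summary$counts),
      percent = as.list(cat_summary$percent),
      prmt5_dependent_aire_share = cat_summary$prmt5_dependent_aire_share
    ),
    diversity = diversity,
    diversity_comparison = list(
      anova = div_comp$anova,
      comparisons = div_comp$comparisons,
      method = div_comp$method
    ),
    correlation = correlation,
    category_retention_tests = cat_tests[, c("category", "genotype",
                                             "n_genes", "p_value",
                                             "q_value", "untestable")]
  )
  if (simulate_mode) {
    report$recovery <- recovery_metrics(categories, ret_fc, truth)
  }
  class(report) <- "run_report"

  state <- list(atlas = atlas, counts = counts, design = design,
                truth = truth, classification = classification,
                expr = expr, expressed = expressed,
                diff_prmt5 = diff_prmt5, diff_aire = diff_aire,
                categories = categories, retention_fc = ret_fc,
                retention_table = ret_table, diversity = diversity)
  attr(report, "state") <- state

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_atlas(atlas, file.path(out_dir, "atlas.tsv"))
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    write_design(design, file.path(out_dir, "design.tsv"))
    utils::write.table(classification, file.path(out_dir, "tra_entropy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff_prmt5, file.path(out_dir, "diff_prmt5.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff_aire, file.path(out_dir, "diff_aire.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(categories, file.path(out_dir, "categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ret_fc, file.path(out_dir, "retention.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cat_tests, file.path(out_dir,
                                            "category_retention_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diversity, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth)) {
      utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a run report to JSON
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (%s mode, seed %d)\n", x$mode, x$seed))
  cat(sprintf("  genes %d, samples %d, TRAs %d, expressed %d\n",
              x$stages$n_genes, x$stages$n_samples, x$stages$n_tra,
              x$stages$n_expressed))
  cat(sprintf("  expressed TRA categories: %s (total %d)\n",
              paste(sprintf("%s=%d", names(x$category_summary$counts),
                            unlist(x$category_summary$counts)),
                    collapse = ", "),
              x$category_summary$total))
  if (!is.null(x$correlation)) {
    cat(sprintf("  retention~expression Pearson r = %.3f (p = %.3g)\n",
                x$correlation$r, x$correlation$p))
  }
  invisible(x)
}

#' Render the report figures
#'
#' Presentational companions of the run report: the two-contrast
#' differential-expression scatter, the retention versus expression change
#' scatter, the top retention panel, and the per-genotype diversity plot.
#' Purely graphical — no numbers beyond the report are computed. Panels
#' without data are skipped with a note.
#'
#' @param report a `run_report` from [run_pipeline()] (with its `"state"`
#'   attribute intact).
#' @param out_dir directory for the PNG files.
#' @return invisible character vector of the written paths.
#' @export
make_report_figures <- function(report, out_dir) {
  state <- attr(report, "state")
  if (is.null(state)) stop("report carries no stage state", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  save_fig <- function(p, name) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 120)
    written <<- c(written, path)
  }

  dp <- state$diff_prmt5
  dp$flag <- ifelse(dp$down, "down", ifelse(dp$up, "up", "ns"))
  eps <- report$thresholds$epsilon
  save_fig(
    ggplot2::ggplot(dp, ggplot2::aes(x = log2(mean_control + eps),
                                     y = log2(mean_ko + eps),
                                     colour = flag)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.6) +
      ggplot2::scale_colour_manual(
        values = c(down = "blue", up = "red", ns = "grey60")) +
      ggplot2::labs(x = "log2 RPKM (control)", y = "log2 RPKM (Prmt5-KO)",
                    title = "Differential expression, Prmt5-KO vs control") +
      ggplot2::theme_minimal(),
    "de_scatter_prmt5.png"
  )

  rf <- state$retention_fc
  tra <- tra_genes(state$classification)
  corr_genes <- intersect(intersect(tra, state$expressed), rf$gene_id)
  if (length(corr_genes) >= 3) {
    dd <- data.frame(
      x = log2(rf[corr_genes, "retention_fc"]),
      y = log2(pmax(dp[corr_genes, "fold_change"], 1e-6))
    )
    save_fig(
      ggplot2::ggplot(dd, ggplot2::aes(x, y)) +
        ggplot2::geom_point(size = 0.5, alpha = 0.6) +
        ggplot2::labs(x = "log2 retention fold change",
                      y = "log2 expression fold change",
                      title = "Retention vs expression change (TRA genes)") +
        ggplot2::theme_minimal(),
      "retention_vs_expression.png"
    )
  } else {
    message("figure skipped: too few TRA genes for the correlation panel")
  }

  tp <- state$retention_table$top_panel
  if (!is.null(tp) && nrow(tp)) {
    tp$gene_id <- factor(tp$gene_id, levels = rev(tp$gene_id))
    save_fig(
      ggplot2::ggplot(tp, ggplot2::aes(x = gene_id, y = retention_fc)) +
        ggplot2::geom_col(fill = "firebrick") +
        ggplot2::coord_flip() +
        ggplot2::labs(x = NULL, y = "retention fold change",
                      title = "Top retention panel (TRA_Prmt5)") +
        ggplot2::theme_minimal(),
      "top_retention_panel.png"
    )
  } else {
    message("figure skipped: empty top retention panel")
  }

  dv <- merge(state$diversity, state$design, by = "sample_id")
  save_fig(
    ggplot2::ggplot(dv, ggplot2::aes(x = genotype, y = H_prime)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(y = "Shannon-Weaver H'",
                    title = "TRA repertoire diversity per sample") +
      ggplot2::theme_minimal(),
    "diversity.png"
  )
  invisible(written)
}
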