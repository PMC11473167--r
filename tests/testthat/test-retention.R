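design_pc <- sample_design(2, c("control", "prmt5_ko"))

counts_from <- function(exon, intron, intronic_length = NULL) {
  genes <- rownames(exon)
  if (is.null(intronic_length)) {
    intronic_length <- setNames(rep(100, length(genes)), genes)
  }
  feature_counts(exon, intron,
                 setNames(rep(500, length(genes)), genes), intronic_length)
}

test_that("retention index pools replicates as a ratio of sums", {
  exon <- matrix(c(9L, 7L, 70L, 30L), 1, 4,
                 dimnames = list("g1", design_pc$sample_id))
  intron <- matrix(c(1L, 3L, 30L, 70L), 1, 4, dimnames = dimnames(exon))
  fc <- counts_from(exon, intron)
  # control replicates (1,9) and (3,7): pooled 4/20
  expect_equal(unname(intron_retention_index(fc, design_pc, "control")), 0.2)
  # mean-of-ratios alternative: (0.1 + 0.3) / 2
  expect_equal(
    unname(intron_retention_index(fc, design_pc, "control",
                                  aggregation = "mean")), 0.2)
  # asymmetric depths distinguish the two aggregations
  expect_equal(unname(intron_retention_index(fc, design_pc, "prmt5_ko")),
               0.5)
  expect_equal(
    unname(intron_retention_index(fc, design_pc, "prmt5_ko",
                                  aggregation = "mean")), 0.5)
  expect_error(intron_retention_index(fc, design_pc, "aire_ko"),
               "unknown genotype")
})

test_that("retention index handles zero and all-exon genes", {
  exon <- matrix(c(25L, 25L, 0L, 0L), 2, 2, byrow = TRUE,
                 dimnames = list(c("clean", "empty"),
                                 design_pc$sample_id[1:2]))
  intron <- matrix(0L, 2, 2, dimnames = dimnames(exon))
  d <- design_pc[1:2, ]
  fc <- counts_from(exon, intron)
  idx <- intron_retention_index(fc, d, "control")
  expect_equal(unname(idx["clean"]), 0)
  expect_true(is.na(idx["empty"]))
})

test_that("minimum read filter is inclusive at the threshold", {
  exon <- matrix(c(5L, 5L, 4L, 5L, 0L, 0L), 3, 2, byrow = TRUE,
                 dimnames = list(c("at", "below", "zero"),
                                 design_pc$sample_id[1:2]))
  intron <- matrix(0L, 3, 2, dimnames = dimnames(exon))
  fc <- counts_from(exon, intron)
  kept <- min_read_filter(fc, design_pc[1:2, ], "control", threshold = 10)
  expect_identical(kept, "at")
})

test_that("retention fold change flags are strict and disjoint", {
  ik <- c(up = 0.30, down = 0.05, flat = 0.10)
  ic <- c(up = 0.10, down = 0.10, flat = 0.10)
  res <- retention_fold_change(ik, ic)
  expect_true(res["up", "increased"])
  expect_false(res["up", "decreased"])
  expect_true(res["down", "decreased"])
  expect_equal(res["flat", "retention_fc"], 1)
  expect_false(res["flat", "increased"] || res["flat", "decreased"])
  expect_false(any(res$increased & res$decreased, na.rm = TRUE))
  # flag calls for these effect sizes are insensitive to the guard choice
  for (eps in c(1e-4, 1e-3, 1e-2)) {
    r <- retention_fold_change(ik, ic, epsilon = eps)
    expect_true(r["up", "increased"] && r["down", "decreased"])
    expect_false(r["flat", "increased"] || r["flat", "decreased"])
  }
})

test_that("deterministic simulation recovers the planted intron fraction", {
  p <- small_params(nb_dispersion = "none")
  ds <- simulate_dataset(p)
  idx_c <- intron_retention_index(ds$counts, ds$design, "control")
  idx_k <- intron_retention_index(ds$counts, ds$design, "prmt5_ko")
  spliced <- ds$truth$spliceable & ds$truth$category != "silent"
  genes <- ds$truth$gene_id[spliced]
  # rounding the expectations perturbs each ratio by at most 0.5 / total
  err_c <- abs(idx_c[genes] - ds$truth$pi_control[match(genes, ds$truth$gene_id)])
  err_k <- abs(idx_k[genes] - ds$truth$pi_prmt5_ko[match(genes, ds$truth$gene_id)])
  expect_lt(max(err_c), 0.02)
  expect_lt(max(err_k), 0.02)
  expect_lt(mean(err_c), 1e-3)
  expect_lt(mean(err_k), 1e-3)
})

test_that("category retention table summarizes classes and ranks the panel", {
  p <- small_params(nb_dispersion = "none")
  ds <- simulate_dataset(p)
  expr <- rpkm(ds$counts)
  cats <- categorize_tras(
    tra_genes(classify_tras(ds$atlas)),
    diff_test(expr, ds$design, c("prmt5_ko", "control")),
    diff_test(expr, ds$design, c("aire_ko", "control")),
    expressed_filter(expr, ds$design)
  )
  tab <- category_retention_table(ds$counts, ds$design, cats)
  # planted Prmt5-dependent genes sit at the deficient fraction in the KO
  expect_equal(unname(tab$means["TRA_Prmt5", "prmt5_ko"]),
               p$deficient_intron_frac, tolerance = 0.01)
  expect_equal(unname(tab$means["TRA_Prmt5", "control"]),
               p$base_intron_frac, tolerance = 0.01)
  expect_equal(unname(tab$means["TRA_other", "prmt5_ko"]),
               p$base_intron_frac, tolerance = 0.01)
  # top panel ordering matches a brute-force sort of the fold changes
  tp <- tab$top_panel
  expect_lte(nrow(tp), 30)
  expect_true(all(diff(tp$retention_fc) <= 0))
  idx_c <- intron_retention_index(ds$counts, ds$design, "control")
  idx_k <- intron_retention_index(ds$counts, ds$design, "prmt5_ko")
  eligible <- intersect(
    setdiff(cats$gene_id[cats$category == "TRA_Prmt5"],
            tab$excluded_intronless),
    min_read_filter(ds$counts, ds$design, "prmt5_ko")
  )
  fc_all <- sort((idx_k[eligible] + 1e-3) / (idx_c[eligible] + 1e-3),
                 decreasing = TRUE)
  expect_equal(tp$retention_fc, unname(fc_all[seq_len(nrow(tp))]))
  # single-exon genes are excluded and reported
  expect_true(all(ds$counts$intronic_length[tab$excluded_intronless] == 0))
})
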