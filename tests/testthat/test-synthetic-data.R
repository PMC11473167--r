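test_that("simulation parameters enforce their invariants", {
  expect_s3_class(simulation_params(), "simulation_params")
  expect_error(simulation_params(frac_tra = 1.2), "proportions")
  expect_error(simulation_params(category_probs = c(0.5, 0.5, 0.1, 0.1)),
               "summing to 1")
  expect_error(simulation_params(n_replicates = 1), "n_replicates")
  expect_error(simulation_params(base_intron_frac = 0.4,
                                 deficient_intron_frac = 0.3),
               "deficient_intron_frac")
  # equality expresses a null configuration and is allowed
  expect_no_error(simulation_params(base_intron_frac = 0.05,
                                    deficient_intron_frac = 0.05))
  expect_error(simulation_params(n_tissues = 3), "n_tissues")
  expect_error(simulation_params(nb_dispersion = -1), "nb_dispersion")
})

test_that("simulated atlas separates planted TRAs from broad genes", {
  p <- small_params()
  sim <- simulate_atlas(p)
  res <- classify_tras(sim$atlas)
  planted <- sim$truth$gene_id[startsWith(sim$truth$category, "tra")]
  h <- setNames(res$entropy, res$gene_id)
  expect_true(all(h[planted] < 3))
  broad <- setdiff(sim$truth$gene_id, planted)
  expect_true(all(h[broad] > 3))
  expect_setequal(tra_genes(res), planted)
  # planted class shares roughly follow category_probs
  expect_equal(length(planted), round(p$frac_tra * p$n_genes))
})

test_that("the same seed reproduces the dataset bit-identically", {
  p <- small_params()
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1$atlas, d2$atlas)
  expect_identical(d1$counts$exon, d2$counts$exon)
  expect_identical(d1$counts$intron, d2$counts$intron)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(small_params(seed = 12))
  expect_false(identical(d1$counts$exon, d3$counts$exon))
})

test_that("simulated gene models are well-formed and non-overlapping", {
  p <- small_params()
  sim <- simulate_atlas(p)
  models <- simulate_gene_models(p, sim$truth)
  g <- models$genes
  expect_setequal(g$gene_id, sim$truth$gene_id)
  # spliceable genes have >= 1 intron; single-exon genes have none
  spliceable <- sim$truth$gene_id[sim$truth$spliceable]
  expect_true(all(g[spliceable, "intronic_length"] > 0))
  single <- sim$truth$gene_id[!sim$truth$spliceable]
  expect_true(all(g[single, "n_exons"] == 1))
  expect_true(all(g[single, "intronic_length"] == 0))
  # exactly n_exons - 1 introns per gene
  n_introns <- table(factor(models$introns$gene_id, levels = g$gene_id))
  expect_equal(as.integer(n_introns), g$n_exons - 1L)
  # genes tiled without overlap
  ord <- order(g$start)
  expect_true(all(g$start[ord][-1] >= g$end[ord][-nrow(g)]))
})

deterministic_truth <- function(category) {
  data.frame(
    gene_id = "geneA", category = category, tra_breadth = 1L,
    baseline_mu = 1000, spliceable = TRUE, stringsAsFactors = FALSE
  )
}

two_exon_models <- function() {
  gene_models(data.frame(
    gene_id = "geneA", chrom = "chrS", strand = "+",
    start = c(0L, 500L), end = c(400L, 900L)
  ))
}

test_that("deterministic counts follow the generative arithmetic", {
  p <- simulation_params(n_genes = 1, nb_dispersion = "none")
  design <- sample_design(2, c("control", "prmt5_ko"))
  cc <- simulate_counts(p, two_exon_models(), design,
                        deterministic_truth("tra_prmt5"))
  # control: mu 1000, pi 0.05 -> (950, 50); KO: mu 200, pi 0.35 -> (130, 70)
  expect_equal(unname(cc$counts$exon["geneA", ]), c(950L, 950L, 130L, 130L))
  expect_equal(unname(cc$counts$intron["geneA", ]), c(50L, 50L, 70L, 70L))
  idx_c <- intron_retention_index(cc$counts, design, "control")
  idx_k <- intron_retention_index(cc$counts, design, "prmt5_ko")
  expect_equal(unname(idx_c), 0.05)
  expect_equal(unname(idx_k), 0.35)
  fc <- retention_fold_change(idx_k, idx_c)
  expect_equal(fc$retention_fc, (0.35 + 1e-3) / (0.05 + 1e-3))
  expect_equal(fc$retention_fc, 7, tolerance = 0.02)
  expect_true(fc$increased)
})

test_that("an unaffected category keeps control-level counts in both KOs", {
  p <- simulation_params(n_genes = 1, nb_dispersion = "none")
  cc <- simulate_counts(p, two_exon_models(), sample_design(2),
                        deterministic_truth("tra_other"))
  expect_true(all(cc$counts$exon == 950L))
  expect_true(all(cc$counts$intron == 50L))
  expect_error(
    simulate_counts(p, two_exon_models(),
                    data.frame(sample_id = "x_1",
                               genotype = factor("mystery_ko"),
                               replicate = 1L),
                    deterministic_truth("tra_other")),
    "unknown genotype"
  )
})

test_that("stochastic counts hit their expectations in the Poisson limit", {
  p <- simulation_params(n_genes = 1, nb_dispersion = 0, seed = 3)
  design <- sample_design(10000, "control")
  truth <- deterministic_truth("tra_other")
  truth$baseline_mu <- 100
  p2 <- simulation_params(n_genes = 1, nb_dispersion = 0,
                          base_intron_frac = 0.2, seed = 3)
  cc <- simulate_counts(p2, two_exon_models(), design, truth)
  expect_equal(mean(cc$counts$intron["geneA", ]), 20, tolerance = 0.01)
  expect_equal(mean(cc$counts$exon["geneA", ]), 80, tolerance = 0.01)
})

test_that("read intervals round-trip through the counting module", {
  p <- small_params(n_genes = 30, mean_depth = 6000, nb_dispersion = 0.1)
  ds <- simulate_dataset(p)
  beds <- simulate_read_intervals(ds$counts, ds$models, read_length = 50,
                                  seed = p$seed)
  recounted <- count_reads(beds, ds$models)
  expect_identical(recounted$exon, ds$counts$exon)
  expect_identical(recounted$intron, ds$counts$intron)
  log <- attr(recounted, "read_log")
  expect_true(all(log$ambiguous == 0))
  expect_true(all(log$intergenic == 0))
})

test_that("zero counts give an empty BED and long reads are rejected", {
  m <- two_exon_models()
  zero <- matrix(0L, 1, 1, dimnames = list("geneA", "s1"))
  fc <- feature_counts(zero, zero, c(geneA = 800), c(geneA = 100))
  beds <- simulate_read_intervals(fc, m, read_length = 50)
  expect_equal(nrow(beds$s1), 0)
  some <- feature_counts(zero + 3L, zero + 2L, c(geneA = 800),
                         c(geneA = 100))
  expect_equal(nrow(simulate_read_intervals(some, m, read_length = 50)$s1), 5)
  expect_error(simulate_read_intervals(some, m, read_length = 150),
               "read length")
})
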