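test_that("Shannon-Weaver index matches closed forms and vegan", {
  expect_equal(shannon_weaver(rep(1, 10)), log(10))
  expect_equal(shannon_weaver(c(7, 0, 0)), 0)
  expect_equal(shannon_weaver(c(0.5, 0.5)), log(2))
  # adding a zero-abundance species changes nothing
  x <- c(3, 1, 4, 1, 5)
  expect_equal(shannon_weaver(c(x, 0)), shannon_weaver(x))
  set.seed(44)
  for (i in 1:25) {
    y <- rgamma(sample(3:40, 1), shape = 0.5)
    expect_equal(shannon_weaver(y), unname(vegan::diversity(y)),
                 tolerance = 1e-12)
  }
  expect_true(is.na(shannon_weaver(c(0, 0))))
  expect_error(shannon_weaver(c(-1, 2)), "non-negative")
})

test_that("TRA diversity drops when a planted subset is silenced", {
  set.seed(91)
  base <- rlnorm(300, 3, 0.5)
  for (i in 1:5) {
    hit <- sample.int(300, 80)
    silenced <- base
    silenced[hit] <- silenced[hit] * 0.05
    expect_lt(shannon_weaver(silenced), shannon_weaver(base))
  }
})

test_that("diversity comparison reduces to a t test with two groups", {
  d <- sample_design(4, c("control", "prmt5_ko"))
  set.seed(8)
  div <- data.frame(sample_id = d$sample_id,
                    H_prime = c(rnorm(4, 5, 0.2), rnorm(4, 4.4, 0.2)),
                    n_tra_expressed = 100L)
  res <- diversity_compare(div, d)
  tt <- t.test(H_prime ~ genotype, data = merge(div, d, by = "sample_id"),
               var.equal = TRUE)
  expect_equal(res$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$anova$p, tt$p.value, tolerance = 1e-8)
  expect_equal(res$comparisons$genotype, "prmt5_ko")
  # with a single comparison Dunnett equals the unadjusted t test
  expect_equal(res$comparisons$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("identical group profiles give a null ANOVA", {
  d <- sample_design(3)
  # every genotype shows the same replicate triple: zero between-group
  # variance with positive residual variance, hence F = 0 and p = 1
  div <- data.frame(sample_id = d$sample_id,
                    H_prime = rep(c(4.9, 5.0, 5.1), times = 3),
                    n_tra_expressed = 50L)
  res <- diversity_compare(div, d)
  expect_equal(res$anova$F, 0, tolerance = 1e-12)
  expect_equal(res$anova$p, 1, tolerance = 1e-10)
  expect_true(all(res$comparisons$p_adj > 0.9))
  expect_error(diversity_compare(div[1:3, ], d[1:3, ]), "2 genotype")
})

test_that("a planted drop in one knockout is detected in that arm only", {
  p <- small_params(
    category_probs = c(prmt5_only = 0.5, aire_only = 0, shared = 0,
                       other = 0.5),
    seed = 21
  )
  ds <- simulate_dataset(p)
  expr <- rpkm(ds$counts)
  tra <- tra_genes(classify_tras(ds$atlas))
  div <- tra_diversity(expr, tra)
  res <- diversity_compare(div, ds$design)
  cmp <- setNames(res$comparisons$p_adj, res$comparisons$genotype)
  est <- setNames(res$comparisons$estimate, res$comparisons$genotype)
  expect_lt(cmp[["prmt5_ko"]], 0.05)
  expect_lt(est[["prmt5_ko"]], 0)
  expect_gt(cmp[["aire_ko"]], 0.05)
})

test_that("pearson correlation matches hand values and cor.test", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_equal(pearson_cor(x, c(2, 1, 4, 3))$r, 0.6)
  set.seed(17)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    a <- rnorm(n)
    b <- rnorm(n) + 0.3 * a
    res <- pearson_cor(a, b)
    ref <- cor.test(a, b)
    expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
  expect_true(is.na(pearson_cor(c(1, 1, 1), c(1, 2, 3))$r))
  expect_error(pearson_cor(1:2, 1:2), "length")
  expect_error(pearson_cor(c(1, NA, 3), 1:3), "finite")
})

test_that("BH q-values match the step-up oracle and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  set.seed(55)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # monotone in rank
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("category retention tests find the planted splicing deficit", {
  # large enough that the smallest dependence class holds tens of genes;
  # a paired rank test over a 3-gene class has no power by construction
  p <- small_params(n_genes = 600, mean_depth = 6e5, seed = 31)
  ds <- simulate_dataset(p)
  expr <- rpkm(ds$counts)
  cats <- categorize_tras(
    tra_genes(classify_tras(ds$atlas)),
    diff_test(expr, ds$design, c("prmt5_ko", "control")),
    diff_test(expr, ds$design, c("aire_ko", "control")),
    expressed_filter(expr, ds$design)
  )
  res <- category_retention_tests(ds$counts, ds$design, cats)
  get <- function(cl, g) res[res$category == cl & res$genotype == g, ]
  expect_lt(get("TRA_Prmt5", "prmt5_ko")$q_value, 0.05)
  expect_lt(get("TRA_shared", "prmt5_ko")$q_value, 0.05)
  expect_gt(get("TRA_Prmt5", "aire_ko")$q_value, 0.05)
  expect_gt(get("TRA_other", "prmt5_ko")$q_value, 0.05)
  expect_lt(get("TRA_Aire", "aire_ko")$q_value, 0.05)
  # q never undercuts p
  ok <- !res$untestable
  expect_true(all(res$q_value[ok] >= res$p_value[ok] - 1e-15))
})

test_that("category retention tests flag identical and tiny classes", {
  exon <- matrix(50L, 4, 4)
  intron <- matrix(5L, 4, 4)
  d <- sample_design(2, c("control", "prmt5_ko"))
  dimnames(exon) <- dimnames(intron) <- list(letters[1:4], d$sample_id)
  fc <- feature_counts(exon, intron, setNames(rep(500, 4), letters[1:4]),
                       setNames(rep(100, 4), letters[1:4]))
  cats <- data.frame(
    gene_id = letters[1:4],
    category = factor(c(rep("TRA_Prmt5", 3), "TRA_other"),
                      levels = trasplice:::tra_category_levels())
  )
  res <- category_retention_tests(fc, d, cats, genotypes = "prmt5_ko")
  r1 <- res[res$category == "TRA_Prmt5", ]
  expect_false(r1$untestable)
  expect_equal(r1$p_value, 1)            # identical distributions
  expect_true(res[res$category == "TRA_other", "untestable"])  # < 3 genes
  expect_true(res[res$category == "TRA_Aire", "untestable"])   # empty
})
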