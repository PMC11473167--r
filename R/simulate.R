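#' Parameters of the synthetic mTEC RNA-seq generator
#'
#' Bundles every knob of the simulator: the planted tissue-atlas structure,
#' the knockout effect sizes, and the count-noise model. Defaults encode the
#' study conditions used throughout the package's recovery tests: 2,000
#' genes, 25% TRAs, three replicates per genotype, a 5-fold loss of affected
#' transcripts (`downreg_fc = 0.2`) coupled to an intron-read fraction
#' rising from 0.05 to 0.35, and about 1,000 expected reads per gene
#' (`mean_depth / n_genes`).
#'
#' @param n_genes,n_tissues numbers of genes and atlas tissues.
#' @param frac_tra proportion of genes planted as tissue-restricted.
#' @param tra_breadth candidate numbers of tissues a TRA is expressed in.
#' @param category_probs probabilities over the four TRA dependence classes
#'   `prmt5_only`, `aire_only`, `shared`, `other`; must sum to 1. Defaults
#'   follow the empirical class shares of the mTEC-hi compartment.
#' @param frac_silent proportion of (non-TRA) genes present in the atlas but
#'   silent in the mTEC count data.
#' @param downreg_fc multiplicative factor on the expected total reads of an
#'   affected gene in the genotype(s) that regulate it.
#' @param base_intron_frac intron-read fraction of a normally spliced gene.
#' @param deficient_intron_frac intron-read fraction of a splicing-deficient
#'   gene in the affected genotype; must be `>=` `base_intron_frac`
#'   (equality expresses a null configuration).
#' @param mean_depth expected total reads per sample.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); `0` gives Poisson noise and `"none"` the
#'   deterministic mode (counts equal rounded expectations).
#' @param n_replicates samples per genotype (>= 2).
#' @param tra_high,tra_low atlas expression levels of a TRA gene inside and
#'   outside its expressing tissues.
#' @param frac_single_exon proportion of non-TRA genes modelled without
#'   introns (excluded from retention analysis by construction).
#' @param read_length read length (bp) used when emitting read intervals.
#' @param seed integer seed; all sub-generators derive named substreams
#'   from it.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_genes = 2000,
                              n_tissues = 24,
                              frac_tra = 0.25,
                              tra_breadth = 1:3,
                              category_probs = c(prmt5_only = 0.06,
                                                 aire_only = 0.20,
                                                 shared = 0.23,
                                                 other = 0.51),
                              frac_silent = 0.025,
                              downreg_fc = 0.2,
                              base_intron_frac = 0.05,
                              deficient_intron_frac = 0.35,
                              mean_depth = 2e6,
                              nb_dispersion = 0.1,
                              n_replicates = 3,
                              tra_high = 100,
                              tra_low = 1,
                              frac_single_exon = 0.05,
                              read_length = 50,
                              seed = 1) {
  p <- list(
    n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
    frac_tra = frac_tra, tra_breadth = as.integer(tra_breadth),
    category_probs = category_probs, frac_silent = frac_silent,
    downreg_fc = downreg_fc, base_intron_frac = base_intron_frac,
    deficient_intron_frac = deficient_intron_frac, mean_depth = mean_depth,
    nb_dispersion = nb_dispersion, n_replicates = as.integer(n_replicates),
    tra_high = tra_high, tra_low = tra_low,
    frac_single_exon = frac_single_exon,
    read_length = as.integer(read_length), seed = as.integer(seed)
  )
  props <- c(p$frac_tra, p$frac_silent, p$base_intron_frac,
             p$deficient_intron_frac, p$frac_single_exon)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  if (p$n_genes < 1 || p$n_tissues < 4) {
    stop("need n_genes >= 1 and n_tissues >= 4", call. = FALSE)
  }
  if (length(p$category_probs) != 4 ||
      abs(sum(p$category_probs) - 1) > 1e-9 || any(p$category_probs < 0)) {
    stop("category_probs must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (p$n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (p$deficient_intron_frac < p$base_intron_frac) {
    stop("deficient_intron_frac must be >= base_intron_frac", call. = FALSE)
  }
  if (!identical(p$nb_dispersion, "none") &&
      (!is.numeric(p$nb_dispersion) || p$nb_dispersion < 0)) {
    stop("nb_dispersion must be a non-negative number or \"none\"",
         call. = FALSE)
  }
  if (p$tra_high <= p$tra_low || p$tra_low < 0) {
    stop("need tra_high > tra_low >= 0", call. = FALSE)
  }
  class(p) <- "simulation_params"
  p
}

#' Genotype design of a simulated experiment
#'
#' @param n_replicates samples per genotype.
#' @param genotypes genotype labels; the first level is the control.
#' @return data frame with `sample_id`, `genotype` (factor), `replicate`.
#' @export
sample_design <- function(n_replicates = 3,
                          genotypes = c("control", "prmt5_ko", "aire_ko")) {
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  data.frame(
    sample_id = paste(rep(genotypes, each = n_replicates),
                      seq_len(n_replicates), sep = "_"),
    genotype = factor(rep(genotypes, each = n_replicates),
                      levels = genotypes),
    replicate = rep(seq_len(n_replicates), times = length(genotypes)),
    stringsAsFactors = FALSE
  )
}

# Genotypes in which each planted category is downregulated and
# splicing-deficient.
affected_genotypes <- function() {
  list(control = character(0),
       prmt5_ko = c("tra_prmt5", "tra_shared"),
       aire_ko = c("tra_aire", "tra_shared"))
}

#' Simulate a multi-tissue expression atlas with planted TRA genes
#'
#' TRA-designated genes get expression `tra_high` in `tra_breadth` randomly
#' chosen tissues and `tra_low` elsewhere (with mild multiplicative jitter),
#' yielding low Shannon entropy; the remaining genes are approximately
#' uniform across tissues and score near `log2(n_tissues)` bits. The
#' returned truth table also plants each gene's dependence category and its
#' baseline mTEC expression, which downstream simulators consume.
#'
#' @param params a [simulation_params()] object.
#' @return list with `atlas` (a [tissue_atlas()]) and `truth` (per-gene
#'   `category`, `tra_breadth`, `baseline_mu`, `spliceable`).
#' @export
simulate_atlas <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(substream_seed(params$seed, 1))
  n <- params$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  tissue_ids <- sprintf("tissue%02d", seq_len(params$n_tissues))

  category <- rep("non_tra", n)
  n_tra <- round(params$frac_tra * n)
  tra_idx <- sort(sample.int(n, n_tra))
  category[tra_idx] <- sample(
    c("tra_prmt5", "tra_aire", "tra_shared", "tra_other"),
    n_tra, replace = TRUE, prob = params$category_probs
  )
  non_tra_idx <- setdiff(seq_len(n), tra_idx)
  n_silent <- min(round(params$frac_silent * n), length(non_tra_idx))
  silent_idx <- sort(sample(non_tra_idx, n_silent))
  category[silent_idx] <- "silent"

  values <- matrix(0, n, params$n_tissues,
                   dimnames = list(gene_ids, tissue_ids))
  breadth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    jitter <- stats::runif(params$n_tissues, 0.9, 1.1)
    if (startsWith(category[i], "tra")) {
      b <- if (length(params$tra_breadth) == 1) params$tra_breadth else
        sample(params$tra_breadth, 1)
      breadth[i] <- b
      on_tissues <- sample.int(params$n_tissues, b)
      row <- rep(params$tra_low, params$n_tissues)
      row[on_tissues] <- params$tra_high
      values[i, ] <- row * jitter
    } else {
      values[i, ] <- jitter
    }
  }

  # mTEC baseline expression: lognormal weights scaled to the target depth
  w <- stats::rlnorm(n, meanlog = 0, sdlog = 0.6)
  w[silent_idx] <- 0
  baseline <- params$mean_depth * w / sum(w)

  spliceable <- rep(TRUE, n)
  single <- stats::runif(n) < params$frac_single_exon
  spliceable[category %in% c("non_tra", "silent") & single] <- FALSE

  truth <- data.frame(
    gene_id = gene_ids, category = category, tra_breadth = breadth,
    baseline_mu = baseline, spliceable = spliceable,
    stringsAsFactors = FALSE
  )
  list(atlas = tissue_atlas(values), truth = truth)
}

#' Simulate gene models on a synthetic chromosome
#'
#' Genes are tiled along one synthetic chromosome with fixed spacers.
#' Spliceable genes receive 2-6 exons (lengths 100-300 bp) separated by
#' introns of 100-400 bp, so every feature comfortably exceeds the default
#' read length; non-spliceable genes get a single exon and therefore zero
#' intronic length.
#'
#' @param params a [simulation_params()] object.
#' @param truth truth table from [simulate_atlas()] (uses `gene_id`,
#'   `spliceable`).
#' @return a [gene_models()] object.
#' @export
simulate_gene_models <- function(params, truth) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(substream_seed(params$seed, 2))
  spacer <- 1000L
  cursor <- 0L
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    n_exons <- if (truth$spliceable[i]) sample(2:6, 1) else 1L
    exon_len <- sample(100:300, n_exons, replace = TRUE)
    intron_len <- if (n_exons > 1) {
      sample(100:400, n_exons - 1, replace = TRUE)
    } else {
      integer(0)
    }
    starts <- integer(n_exons)
    ends <- integer(n_exons)
    pos <- cursor
    for (k in seq_len(n_exons)) {
      starts[k] <- pos
      ends[k] <- pos + exon_len[k]
      pos <- ends[k] + if (k < n_exons) intron_len[k] else 0L
    }
    rows[[i]] <- data.frame(
      gene_id = truth$gene_id[i], chrom = "chrS",
      strand = sample(c("+", "-"), 1),
      start = starts, end = ends, stringsAsFactors = FALSE
    )
    cursor <- pos + spacer
  }
  gene_models(do.call(rbind, rows))
}

# Hierarchical count draw: total reads carry the (biological) NB noise,
# the intron/exon split is a per-read Bernoulli with probability pi, so the
# splicing ratio carries only sampling noise. Marginal expectations are
# mu * pi (intron) and mu * (1 - pi) (exon); with Poisson totals the
# marginals are exactly Poisson by thinning.
draw_feature_counts <- function(mu, pi, dispersion) {
  if (identical(dispersion, "none")) {
    total <- round(mu)
    intron <- round(total * pi)
  } else {
    total <- if (dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    intron <- stats::rbinom(length(total), size = total, prob = pi)
  }
  list(exon = as.integer(total - intron), intron = as.integer(intron))
}

#' Simulate exon/intron counts with genotype-specific effects
#'
#' For gene \eqn{g} in a sample of genotype \eqn{G}, the expected total
#' reads are \eqn{\mu_{gG} = b_g \cdot f} with `f = downreg_fc` when the
#' gene's planted category is regulated by \eqn{G} and 1 otherwise; the
#' expectation is split into intron reads \eqn{\mu \pi} and exon reads
#' \eqn{\mu (1 - \pi)}, where \eqn{\pi} is `deficient_intron_frac` for a
#' splicing-deficient gene in the affected genotype and `base_intron_frac`
#' otherwise (and 0 for intronless genes). Total reads are drawn
#' negative-binomially (Poisson when `nb_dispersion = 0`, rounded
#' expectations in deterministic mode `nb_dispersion = "none"`), and the
#' intron reads are a binomial split of the total with probability
#' \eqn{\pi}: biological noise lives in the total, the splicing ratio
#' carries only sampling noise. Loss of mature signal is thereby coupled to
#' the rise in intron-read fraction, the inverse relation the retention
#' analysis is designed to detect.
#'
#' @param params a [simulation_params()] object.
#' @param models a [gene_models()] object for the truth genes.
#' @param design a [sample_design()] data frame; genotypes must be among
#'   control/prmt5_ko/aire_ko.
#' @param truth truth table from [simulate_atlas()].
#' @return list with `counts` (a [feature_counts()]) and `truth`: the input
#'   truth augmented with per-genotype `mu_<genotype>` and `pi_<genotype>`
#'   columns.
#' @export
simulate_counts <- function(params, models, design, truth) {
  stopifnot(inherits(params, "simulation_params"))
  aff <- affected_genotypes()
  genos <- as.character(unique(design$genotype))
  if (!all(genos %in% names(aff))) {
    stop("unknown genotype(s): ",
         paste(setdiff(genos, names(aff)), collapse = ", "), call. = FALSE)
  }
  set.seed(substream_seed(params$seed, 3))
  gene_ids <- truth$gene_id
  has_intron <- models$genes[gene_ids, "intronic_length"] > 0

  mu_geno <- list()
  pi_geno <- list()
  for (g in genos) {
    hit <- truth$category %in% aff[[g]]
    mu_geno[[g]] <- truth$baseline_mu * ifelse(hit, params$downreg_fc, 1)
    pi_geno[[g]] <- ifelse(
      has_intron & truth$spliceable,
      ifelse(hit, params$deficient_intron_frac, params$base_intron_frac),
      0
    )
  }

  exon <- matrix(0L, length(gene_ids), nrow(design),
                 dimnames = list(gene_ids, design$sample_id))
  intron <- exon
  for (s in seq_len(nrow(design))) {
    g <- as.character(design$genotype[s])
    drawn <- draw_feature_counts(mu_geno[[g]], pi_geno[[g]],
                                 params$nb_dispersion)
    exon[, s] <- drawn$exon
    intron[, s] <- drawn$intron
  }

  for (g in genos) {
    truth[[paste0("mu_", g)]] <- mu_geno[[g]]
    truth[[paste0("pi_", g)]] <- pi_geno[[g]]
  }
  counts <- feature_counts(
    exon, intron,
    stats::setNames(models$genes[gene_ids, "exonic_length"], gene_ids),
    stats::setNames(models$genes[gene_ids, "intronic_length"], gene_ids)
  )
  list(counts = counts, truth = truth)
}

#' Emit read intervals realizing a count matrix
#'
#' Places, for every gene and sample, exactly `exon` reads fully inside the
#' gene's exons and `intron` reads fully inside its introns, so that
#' re-counting the intervals with [count_reads()] reproduces the input
#' matrix bit-exactly.
#'
#' @param counts a [feature_counts()] object.
#' @param models the matching [gene_models()] object.
#' @param read_length read length in bp; must not exceed the smallest
#'   feature that carries reads.
#' @param seed integer seed.
#' @return named list (per sample) of BED-like data frames with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
simulate_read_intervals <- function(counts, models, read_length = 50,
                                    seed = 1) {
  stopifnot(inherits(counts, "feature_counts"))
  gene_ids <- rownames(counts$exon)
  if (!all(gene_ids %in% models$genes$gene_id)) {
    stop("every counted gene needs a gene model", call. = FALSE)
  }
  set.seed(substream_seed(seed, 4))
  exons_by_gene <- split(models$exons, models$exons$gene_id)
  introns_by_gene <- split(models$introns, models$introns$gene_id)

  place <- function(feat, k, gene, what) {
    widths <- feat$end - feat$start
    ok <- widths >= read_length
    if (!any(ok)) {
      stop(sprintf("read length %d exceeds every %s of gene %s",
                   read_length, what, gene), call. = FALSE)
    }
    feat <- feat[ok, , drop = FALSE]
    widths <- widths[ok]
    idx <- sample.int(nrow(feat), k, replace = TRUE,
                      prob = widths - read_length + 1)
    offs <- floor(stats::runif(k) * (widths[idx] - read_length + 1))
    data.frame(chrom = feat$chrom[idx],
               start = feat$start[idx] + as.integer(offs),
               strand = feat$strand[idx], stringsAsFactors = FALSE)
  }

  out <- stats::setNames(vector("list", ncol(counts$exon)),
                         colnames(counts$exon))
  for (s in seq_len(ncol(counts$exon))) {
    pieces <- list()
    for (gi in seq_along(gene_ids)) {
      g <- gene_ids[gi]
      ke <- counts$exon[gi, s]
      ki <- counts$intron[gi, s]
      if (ke > 0) pieces[[length(pieces) + 1L]] <-
          place(exons_by_gene[[g]], ke, g, "exon")
      if (ki > 0) {
        intr <- introns_by_gene[[g]]
        if (is.null(intr) || !nrow(intr)) {
          stop(sprintf("gene %s has intron reads but no introns", g),
               call. = FALSE)
        }
        pieces[[length(pieces) + 1L]] <- place(intr, ki, g, "intron")
      }
    }
    bed <- if (length(pieces)) do.call(rbind, pieces) else
      data.frame(chrom = character(0), start = integer(0),
                 strand = character(0))
    bed$end <- bed$start + read_length
    n <- nrow(bed)
    out[[s]] <- data.frame(
      chrom = bed$chrom, start = bed$start, end = bed$end,
      name = if (n) sprintf("read%07d", seq_len(n)) else character(0),
      score = rep(0L, n), strand = bed$strand,
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running atlas, gene-model, design and count
#' simulation from one parameter set.
#'
#' @param params a [simulation_params()] object.
#' @return list with `atlas`, `models`, `design`, `counts`, `truth`.
#' @export
simulate_dataset <- function(params = simulation_params()) {
  atl <- simulate_atlas(params)
  models <- simulate_gene_models(params, atl$truth)
  design <- sample_design(params$n_replicates)
  cc <- simulate_counts(params, models, design, atl$truth)
  list(atlas = atl$atlas, models = models, design = design,
       counts = cc$counts, truth = cc$truth)
}
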