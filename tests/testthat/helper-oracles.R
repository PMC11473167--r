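# Independent oracles and small fixture builders shared across tests.

# Literal high-precision Shannon entropy: explicit loop over terms.
oracle_entropy <- function(x, base = 2) {
  tot <- sum(x)
  if (tot == 0) return(NA_real_)
  h <- 0
  for (xi in x) {
    if (xi > 0) {
      p <- xi / tot
      h <- h - p * log(p) / log(base)
    }
  }
  h
}

# Brute-force read assignment: per read, per gene, per base. Mirrors the
# documented rules (ambiguous multi-gene reads discarded; any intron base
# => intronic; fully inside exon union => exonic) without interval algebra.
oracle_count <- function(bed, models) {
  gene_ids <- models$genes$gene_id
  exon <- setNames(integer(length(gene_ids)), gene_ids)
  intron <- exon
  tallies <- c(ambiguous = 0L, intergenic = 0L, boundary = 0L)
  for (r in seq_len(nrow(bed))) {
    bases <- seq(bed$start[r], bed$end[r] - 1)
    hits <- character(0)
    for (g in gene_ids) {
      gm <- models$genes[g, ]
      if (gm$chrom == bed$chrom[r] &&
          any(bases >= gm$start & bases < gm$end)) {
        hits <- c(hits, g)
      }
    }
    if (length(hits) == 0) {
      tallies["intergenic"] <- tallies["intergenic"] + 1L
    } else if (length(hits) > 1) {
      tallies["ambiguous"] <- tallies["ambiguous"] + 1L
    } else {
      g <- hits
      intr <- models$introns[models$introns$gene_id == g, , drop = FALSE]
      in_intron <- FALSE
      if (nrow(intr)) {
        for (k in seq_len(nrow(intr))) {
          if (any(bases >= intr$start[k] & bases < intr$end[k])) {
            in_intron <- TRUE
          }
        }
      }
      if (in_intron) {
        intron[g] <- intron[g] + 1L
      } else {
        ex <- models$exons[models$exons$gene_id == g, , drop = FALSE]
        covered <- rep(FALSE, length(bases))
        for (k in seq_len(nrow(ex))) {
          covered <- covered | (bases >= ex$start[k] & bases < ex$end[k])
        }
        if (all(covered)) {
          exon[g] <- exon[g] + 1L
        } else {
          tallies["boundary"] <- tallies["boundary"] + 1L
        }
      }
    }
  }
  list(exon = exon, intron = intron, tallies = tallies)
}

# Two-gene fixture used across the counting tests:
# geneA: exons [100,200) and [300,400) with intron [200,300)
# geneB: single exon [600,800)
tiny_models <- function() {
  gene_models(data.frame(
    gene_id = c("geneA", "geneA", "geneB"),
    chrom = "chrS", strand = "+",
    start = c(100L, 300L, 600L),
    end = c(200L, 400L, 800L)
  ))
}

# Random small instance generator for property tests.
random_instance <- function(n_genes = 8, n_reads = 300, seed = 1) {
  set.seed(seed)
  exons <- list()
  cursor <- 0L
  for (g in seq_len(n_genes)) {
    n_ex <- sample(1:4, 1)
    pos <- cursor
    for (k in seq_len(n_ex)) {
      len <- sample(30:120, 1)
      exons[[length(exons) + 1L]] <- data.frame(
        gene_id = sprintf("g%02d", g), chrom = "chrS", strand = "+",
        start = pos, end = pos + len
      )
      pos <- pos + len + if (k < n_ex) sample(20:100, 1) else 0L
    }
    # occasional small spacer so some reads straddle adjacent genes
    cursor <- pos + sample(c(5L, 10L, 200L), 1)
  }
  models <- gene_models(do.call(rbind, exons))
  span <- max(models$genes$end) + 100L
  starts <- sample.int(span, n_reads, replace = TRUE) - 1L
  widths <- sample(15:60, n_reads, replace = TRUE)
  bed <- data.frame(chrom = "chrS", start = starts, end = starts + widths)
  list(models = models, bed = bed)
}

small_params <- function(n_genes = 200, mean_depth = 2e5, seed = 11, ...) {
  simulation_params(n_genes = n_genes, mean_depth = mean_depth, seed = seed,
                    ...)
}
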