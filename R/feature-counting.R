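#' Derive intron intervals from a gene's exons
#'
#' Introns are the gaps between consecutive exons after sorting and merging
#' overlapping or abutting exons. Coordinates are 0-based half-open
#' throughout (BED convention). A single-exon gene has no introns.
#'
#' @param exons data frame or matrix with columns `start`, `end`
#'   (0-based half-open) for one gene.
#' @return data frame with columns `start`, `end` for each intron
#'   (0-based half-open); zero rows for single-exon genes.
#' @examples
#' derive_introns(data.frame(start = c(100, 300), end = c(200, 400)))
#' @export
derive_introns <- function(exons) {
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    stop("exons need 'start' and 'end' columns", call. = FALSE)
  }
  if (nrow(exons) == 0) stop("a gene needs at least one exon", call. = FALSE)
  if (any(exons$end <= exons$start)) {
    stop("malformed exon interval (end <= start)", call. = FALSE)
  }
  merged <- IRanges::reduce(
    IRanges::IRanges(start = exons$start + 1L, end = exons$end)
  )
  n <- length(merged)
  if (n < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # gap between merged exon i and i+1, back in 0-based half-open coordinates
  data.frame(
    start = IRanges::end(merged)[-n],
    end = IRanges::start(merged)[-1] - 1L
  )
}

#' Build gene models from an exon table
#'
#' A gene model is a set of merged exons on one chromosome plus the introns
#' derived between them. Exonic and intronic lengths (bp) are precomputed;
#' they are the denominators of RPKM and the substrate of intron-retention
#' analysis.
#'
#' @param exons data frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open) and optionally `chrom` (default `"chrS"`) and
#'   `strand` (default `"+"`).
#' @return a `gene_models` object: list with `exons`, `introns` (per-gene
#'   interval tables) and `genes` (per-gene extent, `exonic_length`,
#'   `intronic_length`, `n_exons`).
#' @export
gene_models <- function(exons) {
  exons <- as.data.frame(exons)
  req <- c("gene_id", "start", "end")
  if (!all(req %in% names(exons))) {
    stop("exon table needs columns gene_id, start, end", call. = FALSE)
  }
  if (is.null(exons$chrom)) exons$chrom <- "chrS"
  if (is.null(exons$strand)) exons$strand <- "+"
  if (any(exons$end <= exons$start)) {
    stop("malformed exon interval (end <= start)", call. = FALSE)
  }
  split_ex <- split(exons, exons$gene_id)
  per_gene <- lapply(names(split_ex), function(g) {
    ex <- split_ex[[g]]
    if (length(unique(ex$chrom)) != 1 || length(unique(ex$strand)) != 1) {
      stop(sprintf("gene %s spans multiple chromosomes or strands", g),
           call. = FALSE)
    }
    merged <- IRanges::reduce(
      IRanges::IRanges(start = ex$start + 1L, end = ex$end)
    )
    mex <- data.frame(
      gene_id = g, chrom = ex$chrom[1], strand = ex$strand[1],
      start = IRanges::start(merged) - 1L, end = IRanges::end(merged),
      stringsAsFactors = FALSE
    )
    intr <- derive_introns(mex)
    introns <- if (nrow(intr)) {
      data.frame(gene_id = g, chrom = ex$chrom[1], strand = ex$strand[1],
                 start = intr$start, end = intr$end, stringsAsFactors = FALSE)
    } else {
      NULL
    }
    gene <- data.frame(
      gene_id = g, chrom = ex$chrom[1], strand = ex$strand[1],
      start = min(mex$start), end = max(mex$end),
      exonic_length = sum(mex$end - mex$start),
      intronic_length = if (is.null(introns)) 0L else
        sum(introns$end - introns$start),
      n_exons = nrow(mex),
      stringsAsFactors = FALSE
    )
    list(exons = mex, introns = introns, gene = gene)
  })
  out <- list(
    exons = do.call(rbind, lapply(per_gene, `[[`, "exons")),
    introns = do.call(rbind, Filter(Negate(is.null),
                                    lapply(per_gene, `[[`, "introns"))),
    genes = do.call(rbind, lapply(per_gene, `[[`, "gene"))
  )
  if (is.null(out$introns)) {
    out$introns <- data.frame(gene_id = character(0), chrom = character(0),
                              strand = character(0), start = integer(0),
                              end = integer(0))
  }
  rownames(out$genes) <- out$genes$gene_id
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons, %d introns on %s\n",
              nrow(x$genes), nrow(x$exons), nrow(x$introns),
              paste(unique(x$genes$chrom), collapse = ",")))
  invisible(x)
}

#' Construct a paired exon/intron count container
#'
#' @param exon,intron non-negative integer matrices (genes x samples) with
#'   identical dimnames.
#' @param exonic_length,intronic_length named per-gene feature lengths (bp).
#' @return a `feature_counts` object.
#' @export
feature_counts <- function(exon, intron, exonic_length, intronic_length) {
  exon <- as.matrix(exon)
  intron <- as.matrix(intron)
  if (!identical(dim(exon), dim(intron)) ||
      !identical(dimnames(exon), dimnames(intron))) {
    stop("exon and intron matrices must share shape and dimnames",
         call. = FALSE)
  }
  if (is.null(rownames(exon)) || is.null(colnames(exon))) {
    stop("count matrices need gene rownames and sample colnames",
         call. = FALSE)
  }
  if (any(exon < 0) || any(intron < 0) ||
      !is_wholenumber(exon) || !is_wholenumber(intron)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  exonic_length <- exonic_length[rownames(exon)]
  intronic_length <- intronic_length[rownames(exon)]
  if (anyNA(exonic_length) || anyNA(intronic_length)) {
    stop("feature lengths missing for some genes", call. = FALSE)
  }
  structure(
    list(exon = exon, intron = intron,
         exonic_length = exonic_length, intronic_length = intronic_length),
    class = "feature_counts"
  )
}

#' @export
print.feature_counts <- function(x, ...) {
  cat(sprintf("feature_counts: %d genes x %d samples (%.0f reads total)\n",
              nrow(x$exon), ncol(x$exon), sum(x$exon) + sum(x$intron)))
  invisible(x)
}

validate_bed_frame <- function(bed, sample) {
  if (!all(c("chrom", "start", "end") %in% names(bed))) {
    stop(sprintf("sample %s: BED needs chrom/start/end columns", sample),
         call. = FALSE)
  }
  bad <- which(!is.finite(bed$start) | !is.finite(bed$end) |
                 bed$end <= bed$start | bed$start < 0)
  if (length(bad)) {
    stop(sprintf("sample %s: invalid BED interval at line %d",
                 sample, bad[1]), call. = FALSE)
  }
  invisible(bed)
}

# Assign one sample's reads to exon/intron features of one chromosome.
# Returns per-gene tallies plus discard counts.
count_chrom <- function(bed, models) {
  gene_ids <- models$genes$gene_id
  n_reads <- nrow(bed)
  reads_ir <- IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  genes_ir <- IRanges::IRanges(start = models$genes$start + 1L,
                               end = models$genes$end)
  ov <- IRanges::findOverlaps(reads_ir, genes_ir)
  hits_per_read <- tabulate(S4Vectors::queryHits(ov), nbins = n_reads)
  ambiguous <- hits_per_read > 1
  intergenic <- hits_per_read == 0

  exon_tab <- integer(length(gene_ids))
  intron_tab <- integer(length(gene_ids))
  names(exon_tab) <- names(intron_tab) <- gene_ids
  boundary <- 0L

  keep <- !ambiguous[S4Vectors::queryHits(ov)]
  q <- S4Vectors::queryHits(ov)[keep]
  g <- S4Vectors::subjectHits(ov)[keep]
  if (length(q)) {
    # intron overlap: any shared base with an intron of the assigned gene
    intron_gene <- match(models$introns$gene_id, gene_ids)
    is_intronic <- rep(FALSE, length(q))
    if (nrow(models$introns)) {
      introns_ir <- IRanges::IRanges(start = models$introns$start + 1L,
                                     end = models$introns$end)
      iov <- IRanges::findOverlaps(reads_ir[q], introns_ir)
      same_gene <- g[S4Vectors::queryHits(iov)] ==
        intron_gene[S4Vectors::subjectHits(iov)]
      is_intronic[unique(S4Vectors::queryHits(iov)[same_gene])] <- TRUE
    }
    # exon containment: read fully inside the exon union of the assigned gene
    exon_gene <- match(models$exons$gene_id, gene_ids)
    exons_ir <- IRanges::IRanges(start = models$exons$start + 1L,
                                 end = models$exons$end)
    eov <- IRanges::findOverlaps(reads_ir[q], exons_ir)
    esame <- g[S4Vectors::queryHits(eov)] ==
      exon_gene[S4Vectors::subjectHits(eov)]
    ew <- IRanges::width(IRanges::pintersect(
      reads_ir[q][S4Vectors::queryHits(eov)[esame]],
      exons_ir[S4Vectors::subjectHits(eov)[esame]]
    ))
    cover <- numeric(length(q))
    if (length(ew)) {
      agg <- rowsum(ew, group = S4Vectors::queryHits(eov)[esame])
      cover[as.integer(rownames(agg))] <- agg[, 1]
    }
    fully_exonic <- !is_intronic & cover == IRanges::width(reads_ir[q])

    exon_add <- tabulate(g[fully_exonic], nbins = length(gene_ids))
    intron_add <- tabulate(g[is_intronic], nbins = length(gene_ids))
    exon_tab <- exon_tab + exon_add
    intron_tab <- intron_tab + intron_add
    boundary <- sum(!is_intronic & !fully_exonic)
  }
  list(exon = exon_tab, intron = intron_tab,
       ambiguous = sum(ambiguous), intergenic = sum(intergenic),
       boundary = boundary)
}

#' Count reads on exon and intron features
#'
#' Assigns each read interval to a gene and feature class. A read
#' overlapping two or more genes is discarded as ambiguous. For a read
#' hitting exactly one gene: if it overlaps any intron base of that gene it
#' is counted as intronic (a junction-spanning read is direct evidence of a
#' retained intron); if it lies entirely within the gene's exon union it is
#' exonic; a read that overlaps the gene but satisfies neither rule (it
#' overhangs the gene boundary) is left unassigned. Reads overlapping no
#' gene are intergenic. Strand is ignored (unstranded protocol).
#'
#' @param reads a BED-like data frame (`chrom`, `start`, `end`, 0-based
#'   half-open) for one sample, or a named list of such frames (one per
#'   sample).
#' @param models a [gene_models()] object.
#' @return a [feature_counts()] object. Attribute `read_log` is a per-sample
#'   data frame of assigned/ambiguous/intergenic/boundary read tallies, whose
#'   rows each sum to that sample's total input reads.
#' @export
count_reads <- function(reads, models) {
  if (is.data.frame(reads)) reads <- list(sample_1 = reads)
  if (is.null(names(reads)) || any(!nzchar(names(reads)))) {
    stop("samples must be named", call. = FALSE)
  }
  gene_ids <- models$genes$gene_id
  exon <- matrix(0L, nrow = length(gene_ids), ncol = length(reads),
                 dimnames = list(gene_ids, names(reads)))
  intron <- exon
  log_rows <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    bed <- validate_bed_frame(as.data.frame(reads[[i]]), names(reads)[i])
    tall <- list(ambiguous = 0L, intergenic = 0L, boundary = 0L)
    for (chr in unique(c(bed$chrom, models$genes$chrom))) {
      sub_bed <- bed[bed$chrom == chr, , drop = FALSE]
      if (!nrow(sub_bed)) next
      sub_models <- subset_models_chrom(models, chr)
      if (is.null(sub_models)) {
        tall$intergenic <- tall$intergenic + nrow(sub_bed)
        next
      }
      res <- count_chrom(sub_bed, sub_models)
      exon[names(res$exon), i] <- exon[names(res$exon), i] + res$exon
      intron[names(res$intron), i] <- intron[names(res$intron), i] +
        res$intron
      tall$ambiguous <- tall$ambiguous + res$ambiguous
      tall$intergenic <- tall$intergenic + res$intergenic
      tall$boundary <- tall$boundary + res$boundary
    }
    log_rows[[i]] <- data.frame(
      sample_id = names(reads)[i], total = nrow(bed),
      exon = sum(exon[, i]), intron = sum(intron[, i]),
      ambiguous = tall$ambiguous, intergenic = tall$intergenic,
      boundary = tall$boundary, stringsAsFactors = FALSE
    )
  }
  out <- feature_counts(
    exon, intron,
    stats::setNames(models$genes$exonic_length, gene_ids),
    stats::setNames(models$genes$intronic_length, gene_ids)
  )
  attr(out, "read_log") <- do.call(rbind, log_rows)
  out
}

subset_models_chrom <- function(models, chr) {
  keep <- models$genes$chrom == chr
  if (!any(keep)) {
    return(NULL)
  }
  out <- list(
    exons = models$exons[models$exons$chrom == chr, , drop = FALSE],
    introns = models$introns[models$introns$chrom == chr, , drop = FALSE],
    genes = models$genes[keep, , drop = FALSE]
  )
  class(out) <- "gene_models"
  out
}

#' Reads per kilobase of exon per million mapped reads
#'
#' \eqn{RPKM_{gs} = 10^9 \, e_{gs} / (L_s \, l_g)} where \eqn{e_{gs}} is the
#' exon read count, \eqn{l_g} the exonic length in bp and \eqn{L_s} the
#' library size. The library size is the sum of all assigned feature reads
#' (exon plus intron) of the sample, so that intron-retaining transcripts
#' count toward "mapped reads".
#'
#' @param counts a [feature_counts()] object.
#' @return an `expression_table`: list with `rpkm` (genes x samples matrix)
#'   and `library_size` (named per-sample totals).
#' @export
rpkm <- function(counts) {
  stopifnot(inherits(counts, "feature_counts"))
  if (any(counts$exonic_length <= 0)) {
    stop("all scored genes need positive exonic length", call. = FALSE)
  }
  lib <- colSums(counts$exon) + colSums(counts$intron)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(names(lib)[lib == 0], collapse = ", "), call. = FALSE)
  }
  mat <- 1e9 * sweep(counts$exon, 1, counts$exonic_length, "/")
  mat <- sweep(mat, 2, lib, "/")
  structure(list(rpkm = mat, library_size = lib), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (RPKM)\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}
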