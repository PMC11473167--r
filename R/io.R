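#' Read / write a tissue atlas as TSV
#'
#' Layout: a `gene_id` column followed by one column per tissue.
#'
#' @param atlas a [tissue_atlas()].
#' @param path file path.
#' @return `write_atlas` returns `path` invisibly; `read_atlas` a
#'   [tissue_atlas()].
#' @export
write_atlas <- function(atlas, path) {
  df <- data.frame(gene_id = rownames(atlas), unclass(atlas),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  tissue_atlas(as.matrix(df[, -1, drop = FALSE]), gene_ids = df$gene_id,
               tissue_ids = colnames(df)[-1])
}

#' Read / write paired exon/intron counts as TSV
#'
#' Layout: `gene_id`, `exonic_length`, `intronic_length`, then
#' `<sample>_exon` and `<sample>_intron` column pairs.
#'
#' @param counts a [feature_counts()] object.
#' @param path file path.
#' @return `write_counts` returns `path` invisibly; `read_counts` a
#'   [feature_counts()].
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "feature_counts"))
  samples <- colnames(counts$exon)
  df <- data.frame(gene_id = rownames(counts$exon),
                   exonic_length = counts$exonic_length,
                   intronic_length = counts$intronic_length,
                   stringsAsFactors = FALSE)
  for (s in samples) {
    df[[paste0(s, "_exon")]] <- counts$exon[, s]
    df[[paste0(s, "_intron")]] <- counts$intron[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  exon_cols <- grep("_exon$", names(df), value = TRUE)
  samples <- sub("_exon$", "", exon_cols)
  exon <- as.matrix(df[, paste0(samples, "_exon"), drop = FALSE])
  intron <- as.matrix(df[, paste0(samples, "_intron"), drop = FALSE])
  dimnames(exon) <- dimnames(intron) <- list(df$gene_id, samples)
  feature_counts(exon, intron,
                 stats::setNames(df$exonic_length, df$gene_id),
                 stats::setNames(df$intronic_length, df$gene_id))
}

#' Read / write a sample design as TSV
#'
#' @param design a [sample_design()] data frame.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$genotype <- factor(df$genotype, levels = unique(df$genotype))
  df
}

#' Write / read gene models as GTF
#'
#' Exon records only; GTF is 1-based inclusive, converted at this boundary
#' from the package's 0-based half-open internals. `gene_id` and
#' `transcript_id` attributes are emitted (one transcript per gene).
#'
#' @param models a [gene_models()] object.
#' @param path file path.
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "trasplice"
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$transcript_id <- paste0(ex$gene_id, ".t1")
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_gtf
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  gene_models(data.frame(
    gene_id = S4Vectors::mcols(gr)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ))
}

#' Write / read read placements as BED6
#'
#' BED is 0-based half-open, matching the package's internal convention;
#' no conversion beyond the rtracklayer boundary is applied.
#'
#' @param bed a BED-like data frame (`chrom`, `start`, `end`, optionally
#'   `name`, `score`, `strand`).
#' @param path file path.
#' @export
write_bed <- function(bed, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    strand = bed$strand %||% "*"
  )
  S4Vectors::mcols(gr)$name <- bed$name %||% sprintf("read%07d",
                                                     seq_len(nrow(bed)))
  S4Vectors::mcols(gr)$score <- bed$score %||% rep(0L, nrow(bed))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = S4Vectors::mcols(gr)$name %||% NA_character_,
    score = as.integer(S4Vectors::mcols(gr)$score %||% 0L),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
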