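#' Gene-level AS summary
#'
#' Per-type event counts, the percentage of multiexon genes (at least two
#' exons in some isoform) carrying at least one event, and the relationship
#' between genic architecture and splicing: the fraction of ES genes per
#' exon-count bin and of IR genes per intron-count bin, each with the
#' Pearson correlation of bin index against fraction.
#'
#' @param events event table
#' @param transcriptome exon table
#' @return list(type_counts, n_multiexon_genes, n_as_genes, pct_as_genes,
#'   es_by_exon_count, ir_by_intron_count)
#' @export
gene_level_summary <- function(events, transcriptome) {
  type_counts <- table(factor(events$type,
                              levels = c("IR", "ES", "A3SS", "A5SS")))
  nx <- n_exons(transcriptome)
  gene_of_tx <- transcriptome$gene_id[
    match(names(nx), transcriptome$transcript_id)]
  max_exons <- tapply(nx, gene_of_tx, max)
  multi <- names(max_exons)[max_exons >= 2]
  as_genes <- unique(events$gene_id)
  pct <- if (length(multi)) 100 * length(intersect(as_genes, multi)) /
    length(multi) else 0

  ratio_by_bin <- function(type, bins) {
    genes_with <- unique(events$gene_id[events$type == type])
    df <- data.frame(gene = multi, bin = bins[multi],
                     has = multi %in% genes_with)
    agg <- aggregate(has ~ bin, df, mean)
    agg$n_genes <- as.integer(table(df$bin)[as.character(agg$bin)])
    r <- if (nrow(agg) >= 3) suppressWarnings(cor(agg$bin, agg$has)) else NA_real_
    list(table = agg, correlation = r)
  }
  exon_bins <- setNames(as.integer(max_exons), names(max_exons))
  intron_bins <- exon_bins - 1L
  list(
    type_counts = type_counts,
    n_multiexon_genes = length(multi),
    n_as_genes = length(intersect(as_genes, multi)),
    pct_as_genes = pct,
    es_by_exon_count = ratio_by_bin("ES", exon_bins),
    ir_by_intron_count = ratio_by_bin("IR", intron_bins)
  )
}

#' Compare retained-intron lengths with other intron lengths
#'
#' Sample A holds the lengths of introns retained in at least one IR event;
#' sample B the lengths of every other intron of the transcriptome. The two
#' samples are compared with the Wilcoxon rank-sum test.
#'
#' @param events event table (must contain at least one IR event)
#' @param transcriptome exon table
#' @param alternative test alternative for sample A vs sample B
#' @return list(retained, other, test = list(statistic, p_value))
#' @export
intron_length_comparison <- function(events, transcriptome,
                                     alternative = "less") {
  ir <- events[events$type == "IR", , drop = FALSE]
  if (nrow(ir) == 0)
    stop("no IR events detected: retained-intron length comparison ",
         "requires at least one intron-retention event")
  # IR coords: (a, s-1, e+1, b) -> retained intron is (c2+1, c3-1)
  ret_key <- junction_key(ir$chrom, ir$c2 + 1L, ir$c3 - 1L, ir$strand)
  introns <- transcript_introns(transcriptome)
  introns <- unique(introns[, c("chrom", "strand", "start", "end")])
  ikey <- junction_key(introns$chrom, introns$start, introns$end,
                       introns$strand)
  len <- introns$end - introns$start + 1L
  retained <- len[ikey %in% ret_key]
  other <- len[!ikey %in% ret_key]
  test <- wilcoxon_rank_sum(retained, other, alternative = alternative)
  list(retained = retained, other = other, test = test)
}
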