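#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the exact hypergeometric rule (sum of the
#' probabilities of all tables at the observed margins whose probability
#' does not exceed the observed table's). The reported odds ratio is the
#' sample odds ratio ad/bc.
#'
#' @param tab 2x2 matrix of nonnegative integer counts
#' @return list(odds_ratio, p_value)
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be nonnegative integers")
  p <- fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = p)
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties; exact null distribution when min(n, m) <= 10 and the
#' pooled sample has no ties, otherwise the normal approximation with tie
#' and continuity correction.
#'
#' @param a,b numeric samples (non-empty)
#' @param alternative "two.sided", "less" or "greater" (a relative to b)
#' @return list(statistic = rank sum of a, p_value)
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided") {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 10
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = TRUE))
  rs <- sum(rank(c(a, b))[seq_along(a)])
  list(statistic = rs, p_value = res$p.value)
}

#' Annotate stage-specific AS genes with known ripening genes
#'
#' Inner join of the stage-specific gene table with a precomputed homolog
#' map (gene id to ripening gene symbol and pathway), producing a
#' species x pathway x stage table of gene symbols.
#'
#' @param stage_specific_genes data.frame with columns species, gene_id,
#'   stage
#' @param homolog_map data.frame with columns gene_id, symbol, pathway
#' @return data.frame species, pathway, stage, gene_id, symbol
#' @export
cross_reference_gene_list <- function(stage_specific_genes, homolog_map) {
  cols <- c("species", "gene_id", "stage")
  stopifnot(all(cols %in% names(stage_specific_genes)),
            all(c("gene_id", "symbol", "pathway") %in% names(homolog_map)))
  out <- merge(stage_specific_genes[cols], homolog_map, by = "gene_id")
  out <- out[, c("species", "pathway", "stage", "gene_id", "symbol")]
  out <- out[order(out$species, out$pathway, out$stage, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
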