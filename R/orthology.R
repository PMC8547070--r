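#' Reciprocal best hits from pairwise similarity hits
#'
#' A cross-species pair (a, b) is a reciprocal best hit when b is a's
#' best-scoring subject among b's species and vice versa. Ties on bit score
#' are broken by lower e-value, then lexicographic gene id.
#'
#' @param hits data.frame with columns qseqid, sseqid, evalue, bitscore
#' @param gene_species named character vector gene id -> species
#' @param max_evalue e-value cut-off (default 1e-10)
#' @return data.frame gene_a, gene_b (gene_a < gene_b), sorted
#' @export
reciprocal_best_hits <- function(hits, gene_species, max_evalue = 1e-10) {
  h <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  h$qsp <- gene_species[h$qseqid]
  h$ssp <- gene_species[h$sseqid]
  h <- h[!is.na(h$qsp) & !is.na(h$ssp) & h$qsp != h$ssp, , drop = FALSE]
  if (nrow(h) == 0)
    return(data.frame(gene_a = character(), gene_b = character()))
  # best subject per (query, subject species)
  h <- h[order(h$qseqid, h$ssp, -h$bitscore, h$evalue, h$sseqid), ]
  best <- h[!duplicated(paste(h$qseqid, h$ssp)), c("qseqid", "sseqid")]
  bkey <- paste(best$qseqid, best$sseqid)
  mutual <- bkey %in% paste(best$sseqid, best$qseqid)
  pairs <- best[mutual, , drop = FALSE]
  a <- pmin(pairs$qseqid, pairs$sseqid)
  b <- pmax(pairs$qseqid, pairs$sseqid)
  out <- unique(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Resolve one-to-one orthologue tuples
#'
#' Single-copy orthogroups (one gene per represented species, at least two
#' species) pass through unchanged. In multi-copy orthogroups, cross-species
#' gene pairs supported by the configured evidence (default: reciprocal best
#' hit AND synteny) are assembled into connected components; components with
#' at most one gene per species and spanning at least two species become
#' orthologue tuples, others are dropped and logged.
#'
#' @param orthogroups named list og_id -> list(species -> gene ids)
#' @param hits similarity hits (see \code{\link{reciprocal_best_hits}}),
#'   may be NULL when every orthogroup is single-copy
#' @param synteny data.frame gene_a, gene_b (order-free), may be NULL
#' @param gene_species named vector gene -> species
#' @param species species set defining tuple columns (default: union of
#'   orthogroup keys)
#' @param evidence "and" (RBH and synteny, default) or "or"
#' @param max_evalue RBH e-value cut-off
#' @param verbose log dropped components
#' @return data.frame with columns index, og_id and one column per species
#'   (NA where the tuple does not cover the species)
#' @export
resolve_one_to_one <- function(orthogroups, hits = NULL, synteny = NULL,
                               gene_species, species = NULL,
                               evidence = c("and", "or"),
                               max_evalue = 1e-10, verbose = FALSE) {
  evidence <- match.arg(evidence)
  if (is.null(species))
    species <- sort(unique(unlist(lapply(orthogroups, names))))
  all_genes <- unlist(lapply(orthogroups, unlist), use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("gene claimed by two orthogroups: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))

  rbh <- if (!is.null(hits) && nrow(hits))
    reciprocal_best_hits(hits, gene_species, max_evalue) else
      data.frame(gene_a = character(), gene_b = character())
  rbh_key <- paste(rbh$gene_a, rbh$gene_b)
  syn_key <- if (!is.null(synteny) && nrow(synteny))
    paste(pmin(synteny$gene_a, synteny$gene_b),
          pmax(synteny$gene_a, synteny$gene_b)) else character(0)

  tuples <- list()
  for (og in names(orthogroups)) {
    members <- orthogroups[[og]]
    sizes <- vapply(members, length, 1L)
    if (length(members) < 2) next
    if (all(sizes == 1L)) {
      tuples[[length(tuples) + 1L]] <-
        c(og_id = og, vapply(species, function(sp)
          if (!is.null(members[[sp]])) members[[sp]] else NA_character_, ""))
      next
    }
    genes <- unlist(members, use.names = FALSE)
    sp_of <- rep(names(members), sizes)
    names(sp_of) <- genes
    # supported cross-species pairs
    comb <- utils::combn(genes, 2)
    ok <- logical(ncol(comb))
    for (k in seq_len(ncol(comb))) {
      a <- comb[1, k]; b <- comb[2, k]
      if (sp_of[a] == sp_of[b]) next
      key <- paste(min(a, b), max(a, b))
      in_rbh <- key %in% rbh_key
      in_syn <- key %in% syn_key
      ok[k] <- if (evidence == "and") in_rbh && in_syn else in_rbh || in_syn
    }
    if (!any(ok)) next
    # connected components (union-find)
    parent <- setNames(genes, genes)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (k in which(ok)) parent[[find(comb[1, k])]] <- find(comb[2, k])
    roots <- vapply(genes, find, "")
    for (comp in split(genes, roots)) {
      if (length(comp) < 2) next
      csp <- sp_of[comp]
      if (anyDuplicated(csp)) {
        msg("orthology: dropped component in ", og,
            " (several genes from one species): ",
            paste(comp, collapse = ","), verbose = verbose)
        next
      }
      tuples[[length(tuples) + 1L]] <-
        c(og_id = og, vapply(species, function(sp)
          if (sp %in% csp) comp[csp == sp] else NA_character_, ""))
    }
  }
  if (!length(tuples)) {
    out <- data.frame(index = integer(), og_id = character())
    for (sp in species) out[[sp]] <- character()
    return(out)
  }
  df <- as.data.frame(do.call(rbind, tuples), stringsAsFactors = FALSE)
  df <- df[order(df$og_id, apply(df[species], 1, paste, collapse = "|")), ,
           drop = FALSE]
  out <- cbind(index = seq_len(nrow(df)), df)
  rownames(out) <- NULL
  out
}
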