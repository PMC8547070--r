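#' Per-sample binary AS profiles over the orthologue index
#'
#' For each sample, orthologue i gets a 1 when at least one AS event of the
#' corresponding gene (for that sample's species) has a per-sample PSI inside
#' the occurrence window. Orthologues with 0 in every sample are dropped
#' before distance computation.
#'
#' @param psi_by_species named list species -> events x samples PSI matrix
#' @param events_by_species named list species -> event table
#' @param orthologue_index data.frame from \code{\link{resolve_one_to_one}}
#' @param window,tol occurrence window (per-sample rule)
#' @return list(matrix = orthologue x sample 0/1 matrix,
#'   orthologue = kept index rows, sample_species = named vector
#'   sample -> species)
#' @export
build_profiles <- function(psi_by_species, events_by_species, orthologue_index,
                           window = c(0.05, 0.95), tol = 1e-9) {
  species <- names(psi_by_species)
  stopifnot(all(species %in% names(orthologue_index)))
  sample_cols <- unlist(lapply(species, function(sp)
    colnames(psi_by_species[[sp]])))
  if (anyDuplicated(sample_cols)) stop("duplicated sample names across species")
  sample_species <- setNames(
    rep(species, vapply(species, function(sp)
      ncol(psi_by_species[[sp]]), 1L)), sample_cols)
  m <- matrix(0L, nrow = nrow(orthologue_index), ncol = length(sample_cols),
              dimnames = list(orthologue_index$index, sample_cols))
  for (sp in species) {
    psi <- psi_by_species[[sp]]
    if (is.null(psi) || any(dim(psi) == 0)) stop("missing PSI data for ", sp)
    ev <- events_by_species[[sp]]
    occ <- call_occurrence(psi, window, tol)
    occ[is.na(occ)] <- FALSE
    gene_of <- ev$gene_id[match(rownames(occ), ev$event_id)]
    for (s in colnames(psi)) {
      genes_on <- unique(gene_of[occ[, s]])
      m[orthologue_index[[sp]] %in% genes_on, s] <- 1L
    }
  }
  keep <- rowSums(m) > 0
  list(matrix = m[keep, , drop = FALSE],
       orthologue = orthologue_index[keep, , drop = FALSE],
       sample_species = sample_species)
}

#' Binary distance between presence/absence profiles
#'
#' d = (b + c) / (a + b + c) with a = both-present count and b, c the
#' discordant counts; both-absent positions do not contribute. Pairs with an
#' empty union support (both vectors all zero) get distance 0.
#'
#' @param m orthologue x sample 0/1 matrix (samples in columns)
#' @return a \code{dist} object over the samples
#' @export
binary_distance <- function(m) {
  if (ncol(m) < 2) stop("need at least two profiles")
  d <- stats::dist(t(m != 0), method = "binary")
  if (anyNA(d)) {
    message("binary_distance: ", sum(is.na(d)),
            " pair(s) with empty union support set to distance 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Hierarchical clustering of AS profiles
#'
#' Agglomerative clustering of the binary distance matrix; the dendrogram is
#' also returned in Newick form. When species labels are supplied, the
#' species-coherence flag records whether cutting the tree at one cluster
#' per species recovers exactly the species partition.
#'
#' @param d \code{dist} over samples
#' @param linkage "complete" (default), "average" or "single"
#' @param species_labels optional named vector sample -> species
#' @return list(hclust, newick, species_coherent)
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average",
                                                "single"),
                                 species_labels = NULL) {
  linkage <- match.arg(linkage)
  if (anyNA(d)) stop("distance matrix contains NA")
  hc <- hclust(d, method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  coherent <- NA
  if (!is.null(species_labels)) {
    sp <- species_labels[hc$labels]
    k <- length(unique(sp))
    ct <- cutree(hc, k = k)
    tab <- table(ct, sp)
    coherent <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
  }
  list(hclust = hc, newick = nwk, species_coherent = coherent)
}

#' Orthologues with species-specific AS
#'
#' An orthologue is species-specific for species S when its bit is 1 in at
#' least one sample of S and 0 in every sample of every other species.
#'
#' @param profiles result of \code{\link{build_profiles}}
#' @return named list species -> data.frame(index, gene_id) of qualifying
#'   orthologues (gene ids of that species)
#' @export
species_specific_as_genes <- function(profiles) {
  m <- profiles$matrix
  sp_of <- profiles$sample_species[colnames(m)]
  species <- unique(sp_of)
  out <- list()
  for (sp in species) {
    own <- rowSums(m[, sp_of == sp, drop = FALSE]) > 0
    other <- rowSums(m[, sp_of != sp, drop = FALSE]) > 0
    sel <- own & !other
    out[[sp]] <- data.frame(
      index = profiles$orthologue$index[sel],
      gene_id = profiles$orthologue[[sp]][sel])
  }
  out
}
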