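#!/usr/bin/env Rscript
# Resolve one-to-one orthologues (single-copy orthogroups plus RBH- and
# synteny-supported pairs in multi-copy groups), then detect conserved AS
# events across species by local alignment of junction-flanking exon
# sequences within orthogroups, and contrast conserved vs nonconserved PSI
# between stages.
library(fruitsplice)

species <- c("cucumber", "melon", "papaya", "peach")
bundle <- read_bundle("results/bundle", species)
dir.create("results/conserved", recursive = TRUE, showWarnings = FALSE)

gene_species <- unlist(lapply(species, function(s) {
  g <- unique(bundle$species_data[[s]]$reference$gene_id)
  setNames(rep(s, length(g)), g)
}))
idx <- resolve_one_to_one(bundle$orthogroups, bundle$hits, bundle$synteny,
                          gene_species, species = species)
write.table(idx, "results/conserved/orthologue_index.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Resolved", nrow(idx), "orthologue tuples\n")

evs <- list(); flanks <- list(); psis <- list()
for (sp in species) {
  d <- bundle$species_data[[sp]]
  tome <- read_gtf(file.path("results/transcriptomes", paste0(sp, ".gtf")))
  evs[[sp]] <- detect_events(tome)
  psis[[sp]] <- stage_mean_psi(compute_psi(evs[[sp]], d$tpm), d$stage_of)
  flanks[[sp]] <- extract_flanks(evs[[sp]], tome, d$genome, species = sp)
}
matches <- pairwise_flank_similarity(do.call(rbind, flanks))
cc <- detect_conserved(matches, bundle$orthogroups, species)
hc <- call_highly_conserved(cc$clusters, species)

write.table(cc$clusters, "results/conserved/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cc$summary$table, "results/conserved/counts_table.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Conserved clusters:", length(unique(cc$clusters$cluster_id)),
    "; highly conserved (all species):",
    length(unique(hc$cluster_id)), "\n")
print(cc$summary$table)

conserved_ids <- lapply(setNames(species, species), function(sp)
  cc$clusters$event_id[cc$clusters$species == sp])
contrast <- conserved_psi_contrast(psis, conserved_ids)
if (!is.null(contrast$conserved))
  cat("Stage PSI contrast, conserved events: p =",
      signif(contrast$conserved$test$p_value, 3), "\n")
cat("Stage PSI contrast, nonconserved events: p =",
    signif(contrast$nonconserved$test$p_value, 3), "\n")
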