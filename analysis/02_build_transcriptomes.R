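#!/usr/bin/env Rscript
# Build the high-quality transcriptome per species from the per-stage
# assembled transcripts: junction-support filter, >1 TPM in both replicates,
# removal of novel/antisense class codes, removal of unmatched single-exon
# transcripts, then the keep-longer stage merge.
library(fruitsplice)

species <- c("cucumber", "melon", "papaya", "peach")
bundle <- read_bundle("results/bundle", species)
dir.create("results/transcriptomes", recursive = TRUE, showWarnings = FALSE)

for (sp in species) {
  d <- bundle$species_data[[sp]]
  bt <- build_high_quality_transcriptome(d$assembled, d$reference,
                                         d$junctions, d$tpm,
                                         d$stage_columns)
  write_gtf(bt$transcriptome,
            file.path("results/transcriptomes", paste0(sp, ".gtf")))
  write.table(bt$summary,
              file.path("results/transcriptomes",
                        paste0(sp, "_filter_summary.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sp, ":", length(unique(bt$transcriptome$transcript_id)),
      "transcripts,", bt$expressed_genes, "expressed genes;",
      nrow(bt$removals), "transcripts removed (",
      paste(sort(unique(bt$removals$reason)), collapse = "/"), ")\n")
}
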