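#' Pipeline configuration
#'
#' Collects every global threshold of the analysis: the PSI occurrence
#' window, the TPM expression cut-off, the junction-support thresholds, the
#' differential-splicing gates, the flank length range and similarity
#' thresholds, the orthology e-value cut-off, the clustering linkage and
#' the seed.
#'
#' @param species species names
#' @param psi_window inclusive PSI occurrence window
#' @param tpm_min expression threshold (strict, both replicates)
#' @param junction_support c(min both replicates, min single replicate)
#' @param dpsi_min,alpha differential-splicing gates
#' @param flank_range c(min, max) flank length in bp
#' @param min_identity,min_len flank-similarity thresholds
#' @param max_evalue orthology e-value cut-off
#' @param orthology_evidence "and" or "or" (RBH/synteny combination)
#' @param linkage clustering linkage
#' @param seed integer seed
#' @param out_dir optional output directory for pipeline TSVs
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(species = c("cucumber", "melon", "papaya",
                                        "peach"),
                            psi_window = c(0.05, 0.95), tpm_min = 1,
                            junction_support = c(4, 10), dpsi_min = 0.1,
                            alpha = 0.05, flank_range = c(30, 300),
                            min_identity = 0.6, min_len = 100,
                            max_evalue = 1e-10,
                            orthology_evidence = "and",
                            linkage = "complete", seed = 1,
                            out_dir = NULL) {
  stopifnot(psi_window[1] >= 0, psi_window[2] <= 1,
            psi_window[1] <= psi_window[2],
            flank_range[1] < flank_range[2])
  structure(list(species = species, psi_window = psi_window,
                 tpm_min = tpm_min, junction_support = junction_support,
                 dpsi_min = dpsi_min, alpha = alpha,
                 flank_range = flank_range, min_identity = min_identity,
                 min_len = min_len, max_evalue = max_evalue,
                 orthology_evidence = orthology_evidence,
                 linkage = linkage, seed = as.integer(seed),
                 out_dir = out_dir), class = "pipeline_config")
}

#' Load a bundle written by \code{\link{write_bundle}}
#'
#' @param dir bundle directory
#' @param species species names
#' @return a bundle list usable by \code{\link{run_pipeline}}
#' @export
read_bundle <- function(dir, species) {
  fp <- function(...) {
    p <- file.path(dir, paste0(...))
    if (!file.exists(p)) stop("missing bundle file: ", p)
    p
  }
  species_data <- lapply(species, function(s) {
    tpm <- read_tpm(fp(s, "_tpm.tsv"))
    samples <- colnames(tpm)
    stage_of <- setNames(sub(paste0("^", s, "_([a-z]+)_rep[0-9]+$"), "\\1",
                             samples), samples)
    stages <- unique(stage_of)
    list(genome = read_genome(fp(s, "_genome.fa")),
         reference = read_gtf(fp(s, "_reference.gtf")),
         assembled = setNames(lapply(stages, function(st)
           read_gtf(fp(s, "_assembled_", st, ".gtf"))), stages),
         junctions = setNames(lapply(stages, function(st)
           read_junctions(fp(s, "_junctions_", st, ".tsv"))), stages),
         tpm = tpm, samples = samples, stage_of = stage_of,
         stage_columns = setNames(lapply(stages, function(st)
           samples[stage_of == st]), stages))
  })
  names(species_data) <- species
  homolog_path <- file.path(dir, "homolog_map.tsv")
  list(species_data = species_data,
       orthogroups = read_orthogroups(fp("orthogroups.tsv")),
       synteny = read_tsv(fp("synteny.tsv")),
       hits = read_blast_hits(fp("blast_hits.tsv")),
       homolog_map = if (file.exists(homolog_path)) read_tsv(homolog_path)
       else NULL)
}

#' Run the full comparative AS analysis
#'
#' Executes, in order: transcriptome building, event detection, PSI
#' computation, occurrence / stage-specific / differential calls, orthology
#' resolution, conserved-event detection and profile clustering, plus the
#' per-species stage contrast (Fisher) and optional ripening-gene join.
#' Results are returned as one list; when \code{config$out_dir} is set the
#' main tables are also written as TSV files.
#'
#' @param bundle a bundle from \code{\link{simulate_dataset}} or
#'   \code{\link{read_bundle}}
#' @param config a \code{\link{pipeline_config}}
#' @param verbose log stage progress
#' @return list with per-stage results and a run \code{report} data.frame
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  species <- intersect(config$species, names(bundle$species_data))
  if (!length(species)) stop("no configured species present in the bundle")
  report <- list()
  tick <- function(stage, detail = "") {
    msg("[", stage, "] ", detail, verbose = verbose)
    report[[length(report) + 1L]] <<- data.frame(stage = stage,
                                                 status = "ok",
                                                 detail = detail)
  }
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  res <- list(config = config)

  ## 1. transcriptome building
  res$builds <- tryCatch(lapply(setNames(species, species), function(s) {
    d <- bundle$species_data[[s]]
    build_high_quality_transcriptome(
      d$assembled, d$reference, d$junctions, d$tpm, d$stage_columns,
      tpm_min = config$tpm_min,
      min_both = config$junction_support[1],
      min_single = config$junction_support[2])
  }), error = function(e) fail("build", e))
  tick("build", paste0(length(species), " species"))

  ## 2. event detection
  res$events <- tryCatch(lapply(res$builds, function(b)
    detect_events(b$transcriptome)), error = function(e) fail("events", e))
  tick("events", paste0(sum(vapply(res$events, nrow, 1L)), " events"))

  ## 3. PSI
  res$psi <- tryCatch(lapply(setNames(species, species), function(s)
    compute_psi(res$events[[s]], bundle$species_data[[s]]$tpm)),
    error = function(e) fail("psi", e))
  tick("psi")

  ## 4. occurrence, stage-specific, differential, stage contrast
  occ_stage <- list(); res$stage_specific <- list()
  res$differential <- list(); res$stage_contrast <- list()
  for (s in species) {
    d <- bundle$species_data[[s]]
    sp_psi <- stage_mean_psi(res$psi[[s]], d$stage_of)
    occ <- call_occurrence(sp_psi, config$psi_window)
    occ_stage[[s]] <- list(stage_psi = sp_psi, occurrence = occ)
    res$stage_specific[[s]] <- call_stage_specific(occ)
    res$differential[[s]] <- tryCatch(differential_splicing(
      res$psi[[s]], res$events[[s]], d$tpm, d$stage_of,
      alpha = config$alpha, dpsi_min = config$dpsi_min),
      error = function(e) fail("differential", e))
    n_occ <- colSums(occ == TRUE, na.rm = TRUE)
    n_not <- nrow(occ) - n_occ
    tab <- rbind(immature = c(n_occ["immature"], n_not["immature"]),
                 ripe = c(n_occ["ripe"], n_not["ripe"]))
    res$stage_contrast[[s]] <- if (all(rowSums(tab) > 0))
      fisher_exact_2x2(t(tab)) else NULL
  }
  res$occurrence <- occ_stage
  tick("occurrence")

  ## 5. orthology
  gene_species <- unlist(lapply(species, function(s) {
    g <- unique(bundle$species_data[[s]]$reference$gene_id)
    setNames(rep(s, length(g)), g)
  }))
  res$orthologue_index <- tryCatch(resolve_one_to_one(
    bundle$orthogroups, bundle$hits, bundle$synteny, gene_species,
    species = species, evidence = config$orthology_evidence,
    max_evalue = config$max_evalue), error = function(e) fail("orthology", e))
  tick("orthology", paste0(nrow(res$orthologue_index), " tuples"))

  ## 6. conserved events
  res$conserved <- tryCatch({
    flanks <- do.call(rbind, lapply(species, function(s)
      extract_flanks(res$events[[s]], res$builds[[s]]$transcriptome,
                     bundle$species_data[[s]]$genome, species = s,
                     min_len = config$flank_range[1],
                     max_len = config$flank_range[2])))
    matches <- pairwise_flank_similarity(flanks,
                                         min_identity = config$min_identity,
                                         min_len = config$min_len)
    out <- detect_conserved(matches, bundle$orthogroups, species)
    out$highly <- call_highly_conserved(out$clusters, species)
    out$flanks <- flanks
    out
  }, error = function(e) fail("conserved", e))
  n_clusters <- if (nrow(res$conserved$clusters))
    max(res$conserved$clusters$cluster_id) else 0L
  tick("conserved", paste0(n_clusters, " clusters"))

  conserved_ids <- lapply(setNames(species, species), function(s)
    res$conserved$clusters$event_id[res$conserved$clusters$species == s])
  res$psi_contrast <- conserved_psi_contrast(
    lapply(occ_stage, `[[`, "stage_psi"), conserved_ids)
  tick("psi_contrast")

  ## 7. profiles and clustering
  res$profiles <- tryCatch(build_profiles(
    res$psi, res$events, res$orthologue_index,
    window = config$psi_window), error = function(e) fail("profiles", e))
  res$distance <- binary_distance(res$profiles$matrix)
  res$clustering <- hierarchical_cluster(res$distance,
                                         linkage = config$linkage,
                                         res$profiles$sample_species)
  res$species_specific_genes <- species_specific_as_genes(res$profiles)
  tick("profiles", paste0(nrow(res$profiles$matrix), " orthologues"))

  ## 8. ripening-gene join
  res$ripening <- if (!is.null(bundle$homolog_map)) {
    ssg <- do.call(rbind, lapply(species, function(s) {
      lab <- res$stage_specific[[s]]
      sel <- lab %in% c("immature_only", "ripe_only")
      if (!any(sel)) return(NULL)
      ev <- res$events[[s]]
      data.frame(species = s,
                 gene_id = ev$gene_id[match(names(lab)[sel], ev$event_id)],
                 stage = sub("_only", "", as.character(lab[sel])))
    }))
    if (!is.null(ssg) && nrow(ssg))
      cross_reference_gene_list(ssg, bundle$homolog_map) else NULL
  } else NULL
  tick("ripening_join")

  res$report <- do.call(rbind, report)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(res$builds)) {
    write_gtf(res$builds[[s]]$transcriptome,
              file.path(out_dir, paste0(s, "_transcriptome.gtf")))
    write_tsv(res$builds[[s]]$summary,
              file.path(out_dir, paste0(s, "_filter_summary.tsv")))
    ev <- res$events[[s]]
    write_tsv(data.frame(
      seqname = ev$chrom, gene_id = ev$gene_id, event_id = ev$event_id,
      type = ev$type,
      inclusion_transcripts = vapply(ev$inclusion, paste, "",
                                     collapse = ","),
      total_transcripts = vapply(seq_len(nrow(ev)), function(i)
        paste(sort(unique(c(ev$inclusion[[i]], ev$exclusion[[i]]))),
              collapse = ","), "")),
      file.path(out_dir, paste0(s, "_events.tsv")))
    write_tsv(data.frame(event_id = rownames(res$psi[[s]]), res$psi[[s]],
                         check.names = FALSE),
              file.path(out_dir, paste0(s, "_psi.tsv")))
    write_tsv(res$differential[[s]],
              file.path(out_dir, paste0(s, "_differential.tsv")))
  }
  write_tsv(res$orthologue_index, file.path(out_dir, "orthologue_index.tsv"))
  write_tsv(res$conserved$clusters,
            file.path(out_dir, "conserved_clusters.tsv"))
  write_tsv(res$conserved$summary$table,
            file.path(out_dir, "conserved_counts.tsv"))
  write_tsv(data.frame(index = rownames(res$profiles$matrix),
                       res$profiles$matrix, check.names = FALSE),
            file.path(out_dir, "profiles.tsv"))
  writeLines(res$clustering$newick, file.path(out_dir, "dendrogram.nwk"))
  write_tsv(res$report, file.path(out_dir, "run_report.tsv"))
  invisible(out_dir)
}
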