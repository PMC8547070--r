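#' Simulate a complete multi-species AS study bundle
#'
#' Generates, per species: a genome, a reference annotation, per-stage
#' assembled transcript sets (reference isoforms, planted alternative
#' isoforms, artefact transcripts), a transcript TPM table and per-stage
#' junction read-support tables; plus cross-species orthogroups, similarity
#' hits, synteny pairs, a ripening-gene homolog map and a ground-truth
#' manifest. Identical seeds give byte-identical bundles.
#'
#' Every orthogroup has one gene per species sharing the exon/intron
#' architecture and carries one planted AS event: conserved events are
#' planted at the same position in every species with exonic sequence copied
#' from a common ancestor and mutated at \code{flank_divergence}; the other
#' events are planted in a single species. Artefact transcripts come in four
#' flavours matching the four transcript filters.
#'
#' @param config a \code{\link{simulation_config}}
#' @param out_dir optional directory; when given, the full bundle is written
#'   there (FASTA/GTF/TSV + manifest tables)
#' @param verbose log progress
#' @return the bundle: list(config, species_data, orthogroups, synteny,
#'   hits, homolog_map, truth)
#' @export
simulate_dataset <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sp_all <- config$species
  n_og <- config$n_orthogroups
  types <- c("IR", "ES", "A3SS", "A5SS")
  stages <- c("immature", "ripe")
  nrep <- config$n_replicates

  n_cons <- round(config$frac_conserved_events * n_og)
  cons_set <- if (n_cons > 0) sort(sample.int(n_og, n_cons)) else integer(0)
  n_ss <- round(config$frac_stage_specific * n_og)
  ss_set <- if (n_ss > 0) sort(sample.int(n_og, n_ss)) else integer(0)
  n_multi <- round(config$frac_multicopy * n_og)
  multi_set <- if (n_multi > 0) sort(sample.int(n_og, n_multi)) else integer(0)

  ## ---- orthogroup architectures and planted events ----------------------
  ogs <- vector("list", n_og)
  for (i in seq_len(n_og)) {
    n_ex <- sample(4:8, 1)
    ex_len <- sample(120:400, n_ex, replace = TRUE)
    in_len <- sample(500:2000, n_ex - 1, replace = TRUE)
    type <- sample(types, 1, prob = config$event_mix)
    k <- if (type == "ES") sample(2:(n_ex - 1), 1) else
      sample(seq_len(n_ex - 1), 1)
    if (type == "IR") in_len[k] <- sample(80:150, 1) # retained introns short
    shift <- if (type %in% c("A5SS", "A3SS")) sample(30:90, 1) else 0L
    strand <- if (runif(1) < config$frac_minus_strand) "-" else "+"
    conserved <- i %in% cons_set
    ss <- i %in% ss_set
    owner <- if (conserved) sp_all else sample(sp_all, 1)
    if (ss) {
      on_stage <- if (runif(1) < 0.7) "ripe" else "immature"
      off <- if (runif(1) < 0.5) 0.99 else 0.01
      psi <- c(immature = if (on_stage == "immature") 0.5 else off,
               ripe = if (on_stage == "ripe") 0.5 else off)
      label <- paste0(on_stage, "_only")
    } else if (conserved) {
      p <- runif(1, 0.3, 0.7)
      psi <- c(immature = p, ripe = p)
      label <- "both"
    } else {
      p <- runif(1, 0.15, 0.55)
      psi <- c(immature = p, ripe = p + 0.3)
      label <- "both"
    }
    tc <- arch_tcoords(ex_len, in_len)
    anc_exons <- if (conserved) lapply(ex_len, random_dna) else NULL
    ogs[[i]] <- list(id = sprintf("OG%04d", i), n_ex = n_ex,
                     ex_len = ex_len, in_len = in_len, tc = tc,
                     type = type, k = k, shift = shift, strand = strand,
                     conserved = conserved, owner = owner, psi = psi,
                     label = label, anc_exons = anc_exons,
                     multicopy = i %in% multi_set)
  }
  ## extra species-specific genes (no orthologues, no events)
  extras <- lapply(sp_all, function(s) {
    lapply(seq_len(config$genes_per_species_extra), function(j) {
      if (j %% 2 == 1) { # single-exon gene
        list(n_ex = 1L, ex_len = sample(300:800, 1), in_len = integer(0))
      } else {
        n_ex <- sample(4:8, 1)
        list(n_ex = n_ex, ex_len = sample(120:400, n_ex, replace = TRUE),
             in_len = sample(500:2000, n_ex - 1, replace = TRUE))
      }
    })
  })
  names(extras) <- sp_all

  species_data <- list()
  truth_events <- list()
  truth_fates <- list()
  final_transcripts <- list()

  for (s in sp_all) {
    samples <- as.vector(vapply(stages, function(st)
      paste0(s, "_", st, "_rep", seq_len(nrep)), character(nrep)))
    stage_of <- setNames(rep(stages, each = nrep), samples)

    ## gene roster: OG primaries, duplicates, extras
    roster <- list()
    for (i in seq_len(n_og)) {
      og <- ogs[[i]]
      roster[[length(roster) + 1L]] <- list(
        gene = sprintf("%s_g%04d", s, i), og = og$id, arch = og,
        strand = og$strand,
        event = og$conserved || s %in% og$owner, kind = "primary", og_i = i)
      if (og$multicopy)
        roster[[length(roster) + 1L]] <- list(
          gene = sprintf("%s_gd%04d", s, i), og = og$id, arch = og,
          strand = og$strand, event = FALSE, kind = "duplicate", og_i = i)
    }
    for (j in seq_along(extras[[s]])) {
      a <- extras[[s]][[j]]
      roster[[length(roster) + 1L]] <- list(
        gene = sprintf("%s_gx%02d", s, j), og = NA_character_,
        arch = c(a, list(tc = arch_tcoords(a$ex_len, a$in_len))),
        strand = if (runif(1) < config$frac_minus_strand) "-" else "+",
        event = FALSE, kind = "extra", og_i = NA_integer_)
    }

    ## genome assembly: gaps + oriented locus sequences
    chrom <- "chr1"
    pieces <- character(0)
    pos <- 0L
    ref_rows <- list(); alt_rows <- list()
    gene_info <- list()
    for (g in roster) {
      gap <- sample(500:2000, 1)
      pieces <- c(pieces, random_dna(gap))
      gstart <- pos + gap + 1L
      arch <- g$arch
      tc <- arch$tc
      L <- tc$L
      # locus sequence in transcription orientation
      ex_seq <- lapply(seq_len(arch$n_ex), function(j) {
        if (g$kind == "primary" && isTRUE(arch$conserved))
          mutate_dna(arch$anc_exons[[j]], config$flank_divergence)
        else random_dna(arch$ex_len[j])
      })
      in_seq <- lapply(arch$in_len, random_dna)
      locus <- character(2 * arch$n_ex - 1)
      locus[seq(1, length(locus), by = 2)] <- unlist(ex_seq)
      if (arch$n_ex > 1)
        locus[seq(2, length(locus), by = 2)] <- unlist(in_seq)
      locus <- paste(locus, collapse = "")
      pieces <- c(pieces, if (g$strand == "+") locus else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(locus))))
      pos <- gstart + L - 1L

      ref_g <- map_genomic(tc$start, tc$end, gstart, L, g$strand)
      tid <- paste0(g$gene, ".t1")
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = g$gene, chrom = chrom,
        strand = g$strand, start = ref_g[, "start"], end = ref_g[, "end"])
      info <- list(gene = g$gene, og = g$og, kind = g$kind, tid_ref = tid,
                   gstart = gstart, L = L, strand = g$strand,
                   ref_chain = ref_g, arch = arch, event = g$event)
      if (g$event) {
        at <- alt_chain_t(tc, arch$type, arch$k, arch$shift)
        alt_g <- map_genomic(at$start, at$end, gstart, L, g$strand)
        tid2 <- paste0(g$gene, ".t2")
        alt_rows[[length(alt_rows) + 1L]] <- data.frame(
          transcript_id = tid2, gene_id = g$gene, chrom = chrom,
          strand = g$strand, start = alt_g[, "start"], end = alt_g[, "end"])
        co <- event_coords_genomic(arch$type, ref_g, alt_g, g$strand)
        eid <- event_id_string(g$gene, arch$type, chrom, co[1], co[2],
                               co[3], co[4], g$strand)
        # inclusion form: IR = retained (alt); ES/A5SS/A3SS = reference
        incl <- if (arch$type == "IR") tid2 else tid
        excl <- if (arch$type == "IR") tid else tid2
        info$tid_alt <- tid2
        info$event_rec <- data.frame(
          species = s, gene_id = g$gene, og = g$og, event_id = eid,
          type = arch$type, chrom = chrom, strand = g$strand,
          c1 = co[1], c2 = co[2], c3 = co[3], c4 = co[4],
          psi_immature = unname(arch$psi["immature"]),
          psi_ripe = unname(arch$psi["ripe"]),
          stage_label = arch$label, conserved = arch$conserved,
          cluster = if (arch$conserved) arch$id %||% g$og else "",
          inclusion = incl, exclusion = excl, stringsAsFactors = FALSE)
        truth_events[[length(truth_events) + 1L]] <- info$event_rec
      }
      gene_info[[g$gene]] <- info
    }
    genome <- Biostrings::DNAStringSet(
      setNames(paste(pieces, collapse = ""), chrom))
    reference <- validate_exon_table(do.call(rbind, ref_rows))

    ## TPM table
    tpm <- matrix(0, nrow = 0, ncol = length(samples),
                  dimnames = list(NULL, samples))
    add_tpm <- function(tid, values) {
      m <- matrix(values, nrow = 1, dimnames = list(tid, samples))
      tpm <<- rbind(tpm, m)
    }
    for (gi in gene_info) {
      total <- config$tpm_depth * runif(1, 0.5, 2)
      if (gi$event) {
        arch <- gi$arch
        q <- simulate_quantification(arch$psi, config, total)
        cols <- paste0(s, "_", colnames(q))
        incl_tid <- if (arch$type == "IR") gi$tid_alt else gi$tid_ref
        excl_tid <- if (arch$type == "IR") gi$tid_ref else gi$tid_alt
        add_tpm(incl_tid, q["inclusion", ][match(samples, cols)])
        add_tpm(excl_tid, q["exclusion", ][match(samples, cols)])
      } else {
        add_tpm(gi$tid_ref, rep(total, length(samples)))
      }
    }

    ## artefacts
    real_tx <- c(vapply(gene_info, `[[`, "", "tid_ref"),
                 unlist(lapply(gene_info, function(x) x$tid_alt)))
    n_art <- config$n_artifacts_per_stage %||%
      round(config$frac_artifact_transcripts * length(real_tx))
    flavors <- c("JUNC", "TPM", "CLASS", "MONO")
    hosts <- Filter(function(x)
      !x$event && x$arch$n_ex >= 4, gene_info)
    art_rows <- list(immature = list(), ripe = list())
    art_junc_counts <- list() # junction key -> c(rep1, rep2)
    art_fates <- list()
    if (n_art > 0 && length(hosts) == 0)
      stop("no event-free multi-exon gene available to host artefacts")
    for (st in stages) {
      for (ai in seq_len(n_art)) {
        fl <- flavors[(ai - 1) %% 4 + 1]
        host <- hosts[[(ai - 1) %% length(hosts) + 1]]
        ex <- host$ref_chain[order(host$ref_chain[, "start"]), , drop = FALSE]
        tid <- sprintf("%s_art_%s_%02d", s, st, ai)
        if (fl == "JUNC" || fl == "TPM") {
          # skip one internal exon -> one novel junction
          kskip <- if (fl == "JUNC") 2L else 3L
          kskip <- min(kskip, nrow(ex) - 1L)
          keep <- setdiff(seq_len(nrow(ex)), kskip)
          art <- data.frame(transcript_id = tid, gene_id = host$gene,
                            chrom = chrom, strand = host$strand,
                            start = ex[keep, "start"], end = ex[keep, "end"])
          jkey <- junction_key(chrom, ex[kskip - 1L, "end"] + 1L,
                               ex[kskip + 1L, "start"] - 1L, host$strand)
          if (fl == "JUNC") {
            art_junc_counts[[jkey]] <- c(3L, 9L) # fails the keep rule
            add_tpm(tid, rep(5, length(samples)))
          } else {
            art_junc_counts[[jkey]] <- art_junc_counts[[jkey]] %||% c(30L, 30L)
            add_tpm(tid, rep(0.5, length(samples)))
          }
        } else if (fl == "CLASS") {
          # antisense transcript over the host's first two exons
          flip <- if (host$strand == "+") "-" else "+"
          art <- data.frame(transcript_id = tid,
                            gene_id = paste0(tid, "_gene"),
                            chrom = chrom, strand = flip,
                            start = ex[1:2, "start"], end = ex[1:2, "end"])
          jkey <- junction_key(chrom, ex[1, "end"] + 1L,
                               ex[2, "start"] - 1L, flip)
          art_junc_counts[[jkey]] <- c(30L, 30L)
          add_tpm(tid, rep(5, length(samples)))
        } else { # MONO: unmatched single-exon inside the host's first exon
          art <- data.frame(transcript_id = tid, gene_id = host$gene,
                            chrom = chrom, strand = host$strand,
                            start = ex[1, "start"] + 10L,
                            end = ex[1, "start"] + 80L)
          add_tpm(tid, rep(5, length(samples)))
        }
        art_rows[[st]][[length(art_rows[[st]]) + 1L]] <- art
        art_fates[[length(art_fates) + 1L]] <- data.frame(
          species = s, stage = st, transcript_id = tid, fate = "removed",
          reason = fl)
      }
    }

    ## assembled sets per stage (reference isoforms + alt isoforms + artefacts)
    real_set <- rbind(do.call(rbind, ref_rows),
                      if (length(alt_rows)) do.call(rbind, alt_rows))
    assembled <- list()
    for (st in stages) {
      assembled[[st]] <- validate_exon_table(
        rbind(real_set, do.call(rbind, art_rows[[st]])))
    }

    ## junction support tables per stage
    junctions <- list()
    for (st in stages) {
      ji <- transcript_introns(assembled[[st]])
      ju <- unique(ji[, c("chrom", "start", "end", "strand")])
      ju <- ju[order(ju$start, ju$end, ju$strand), , drop = FALSE]
      keys <- junction_key(ju$chrom, ju$start, ju$end, ju$strand)
      c1 <- integer(nrow(ju)); c2 <- integer(nrow(ju))
      for (r in seq_len(nrow(ju))) {
        ov <- art_junc_counts[[keys[r]]]
        if (!is.null(ov)) { c1[r] <- ov[1]; c2[r] <- ov[2] }
        else { c1[r] <- sample(20:80, 1); c2[r] <- sample(20:80, 1) }
      }
      junctions[[st]] <- data.frame(chrom = ju$chrom, start = ju$start,
                                    end = ju$end, strand = ju$strand,
                                    count_rep1 = c1, count_rep2 = c2)
      rownames(junctions[[st]]) <- NULL
    }

    ## expected filter fates for real transcripts (TPM is the only filter a
    ## real transcript can fail, at a stage where its form is near-absent)
    stage_cols <- lapply(stages, function(st)
      paste0(s, "_", st, "_rep", seq_len(nrep)))
    names(stage_cols) <- stages
    kept_by_stage <- list()
    for (st in stages) {
      tx <- unique(assembled[[st]]$transcript_id)
      real <- tx[tx %in% real_tx]
      v <- tpm[real, stage_cols[[st]], drop = FALSE]
      ok <- apply(v > 1, 1, all)
      for (t in real)
        truth_fates[[length(truth_fates) + 1L]] <- data.frame(
          species = s, stage = st, transcript_id = t,
          fate = if (ok[t]) "kept" else "removed",
          reason = if (ok[t]) "" else "TPM")
      kept_by_stage[[st]] <- real[ok]
    }
    truth_fates <- c(truth_fates, art_fates)
    final_transcripts[[s]] <- sort(unique(unlist(kept_by_stage)))

    species_data[[s]] <- list(
      genome = genome, reference = reference, assembled = assembled,
      junctions = junctions, tpm = tpm, samples = samples,
      stage_of = stage_of, stage_columns = stage_cols)
  }

  ## ---- cross-species tables ---------------------------------------------
  orthogroups <- list()
  synteny <- list()
  hits <- list()
  for (i in seq_len(n_og)) {
    og <- ogs[[i]]
    members <- lapply(sp_all, function(s) {
      g <- sprintf("%s_g%04d", s, i)
      if (og$multicopy) c(g, sprintf("%s_gd%04d", s, i)) else g
    })
    names(members) <- sp_all
    orthogroups[[og$id]] <- members
    for (a in seq_len(length(sp_all) - 1)) for (b in seq(a + 1, length(sp_all))) {
      pa <- sprintf("%s_g%04d", sp_all[a], i)
      pb <- sprintf("%s_g%04d", sp_all[b], i)
      synteny[[length(synteny) + 1L]] <- data.frame(
        gene_a = pa, gene_b = pb,
        block_id = paste0("blk_", sp_all[a], "_", sp_all[b]))
      mk_hit <- function(q, su, bits, ev) data.frame(
        qseqid = q, sseqid = su, pident = 90, length = 300, mismatch = 10,
        gapopen = 0, qstart = 1, qend = 300, sstart = 1, send = 300,
        evalue = ev, bitscore = bits)
      hits[[length(hits) + 1L]] <- mk_hit(pa, pb, 500, 1e-100)
      hits[[length(hits) + 1L]] <- mk_hit(pb, pa, 500, 1e-100)
      if (og$multicopy) {
        da <- sprintf("%s_gd%04d", sp_all[a], i)
        db <- sprintf("%s_gd%04d", sp_all[b], i)
        hits[[length(hits) + 1L]] <- mk_hit(da, db, 310, 1e-50)
        hits[[length(hits) + 1L]] <- mk_hit(db, da, 310, 1e-50)
        hits[[length(hits) + 1L]] <- mk_hit(pa, db, 300, 1e-50)
        hits[[length(hits) + 1L]] <- mk_hit(db, pa, 300, 1e-50)
        hits[[length(hits) + 1L]] <- mk_hit(pb, da, 300, 1e-50)
        hits[[length(hits) + 1L]] <- mk_hit(da, pb, 300, 1e-50)
      }
    }
  }
  # sub-threshold noise hits between unrelated genes
  for (z in seq_len(min(5, n_og - 1))) {
    hits[[length(hits) + 1L]] <- data.frame(
      qseqid = sprintf("%s_g%04d", sp_all[1], z),
      sseqid = sprintf("%s_g%04d", sp_all[2], z + 1),
      pident = 40, length = 80, mismatch = 48, gapopen = 2, qstart = 1,
      qend = 80, sstart = 1, send = 80, evalue = 1e-5, bitscore = 60)
  }
  synteny <- do.call(rbind, synteny)
  hits <- do.call(rbind, hits)

  events_df <- do.call(rbind, truth_events)
  rownames(events_df) <- NULL
  clusters_df <- if (!is.null(events_df) && any(events_df$conserved)) {
    cc <- events_df[events_df$conserved, c("cluster", "species", "gene_id",
                                           "event_id", "type")]
    cc[order(cc$cluster, cc$species), ]
  } else data.frame(cluster = character(), species = character(),
                    gene_id = character(), event_id = character(),
                    type = character())
  rownames(clusters_df) <- NULL

  orth_index <- data.frame(index = seq_len(n_og),
                           og_id = vapply(ogs, `[[`, "", "id"))
  for (s in sp_all)
    orth_index[[s]] <- sprintf("%s_g%04d", s, seq_len(n_og))

  homolog_map <- do.call(rbind, lapply(sp_all, function(s) {
    if (is.null(events_df)) return(NULL)
    ev <- events_df[events_df$species == s, , drop = FALSE]
    if (nrow(ev) == 0) return(NULL)
    n <- min(3, nrow(ev))
    cat_sym <- c("PG2a", "LeACS2", "AP2a")
    cat_path <- c("Cell wall structure",
                  "Ethylene biosynthesis and signalling",
                  "Transcription factor")
    data.frame(gene_id = ev$gene_id[seq_len(n)], symbol = cat_sym[seq_len(n)],
               pathway = cat_path[seq_len(n)])
  }))

  fates_df <- do.call(rbind, truth_fates)
  rownames(fates_df) <- NULL

  truth <- list(events = events_df %||% data.frame(),
                clusters = clusters_df,
                orthologue_index = orth_index,
                fates = fates_df %||% data.frame(),
                final_transcripts = final_transcripts)
  bundle <- list(config = config, species_data = species_data,
                 orthogroups = orthogroups, synteny = synteny, hits = hits,
                 homolog_map = homolog_map, truth = truth)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, verbose = verbose)
  bundle
}

#' Write a simulated bundle to disk
#'
#' @param bundle result of \code{\link{simulate_dataset}}
#' @param out_dir output directory (created if needed)
#' @param verbose log files written
#' @return invisibly, the paths written
#' @export
write_bundle <- function(bundle, out_dir, verbose = FALSE) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir)
  paths <- character(0)
  wp <- function(p) { paths <<- c(paths, p); p }
  for (s in names(bundle$species_data)) {
    d <- bundle$species_data[[s]]
    Biostrings::writeXStringSet(d$genome,
      wp(file.path(out_dir, paste0(s, "_genome.fa"))))
    write_gtf(d$reference, wp(file.path(out_dir, paste0(s, "_reference.gtf"))))
    for (st in names(d$assembled)) {
      write_gtf(d$assembled[[st]],
        wp(file.path(out_dir, paste0(s, "_assembled_", st, ".gtf"))))
      write_tsv(d$junctions[[st]],
        wp(file.path(out_dir, paste0(s, "_junctions_", st, ".tsv"))))
    }
    tdf <- data.frame(transcript_id = rownames(d$tpm), d$tpm,
                      check.names = FALSE)
    write_tsv(tdf, wp(file.path(out_dir, paste0(s, "_tpm.tsv"))))
  }
  write_orthogroups(bundle$orthogroups, bundle$config$species,
                    wp(file.path(out_dir, "orthogroups.tsv")))
  write_tsv(bundle$synteny, wp(file.path(out_dir, "synteny.tsv")))
  write.table(bundle$hits, wp(file.path(out_dir, "blast_hits.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(bundle$homolog_map))
    write_tsv(bundle$homolog_map, wp(file.path(out_dir, "homolog_map.tsv")))
  tr <- bundle$truth
  write_tsv(tr$events, wp(file.path(out_dir, "manifest_events.tsv")))
  write_tsv(tr$clusters, wp(file.path(out_dir, "manifest_clusters.tsv")))
  write_tsv(tr$orthologue_index,
            wp(file.path(out_dir, "manifest_orthologue_index.tsv")))
  write_tsv(tr$fates, wp(file.path(out_dir, "manifest_fates.tsv")))
  msg("wrote ", length(paths), " files to ", out_dir, verbose = verbose)
  invisible(paths)
}

#' Simulate per-sample binary AS profiles directly
#'
#' A light-weight generator at the profile level: each orthologue is
#' assigned an "owner" (a species under the species-dominant structure, a
#' stage under the stage-dominant structure); its bit is 1 in the owner's
#' samples and 0 elsewhere, then every bit is flipped independently with
#' probability \code{noise}.
#'
#' @param n_orthologues profile length before all-zero filtering
#' @param species species names
#' @param structure "species" (species-dominant AS) or "stage"
#' @param stages stage names
#' @param n_replicates replicates per stage
#' @param noise bit-flip probability
#' @param seed integer seed
#' @return list(matrix = orthologue x sample 0/1 matrix, sample_species,
#'   sample_stage)
#' @export
simulate_as_profiles <- function(n_orthologues = 200,
                                 species = c("cucumber", "melon", "papaya",
                                             "peach"),
                                 structure = c("species", "stage"),
                                 stages = c("immature", "ripe"),
                                 n_replicates = 2, noise = 0.05, seed = 1) {
  structure <- match.arg(structure)
  set.seed(seed)
  grid <- expand.grid(rep = seq_len(n_replicates), stage = stages,
                      species = species, stringsAsFactors = FALSE)
  samples <- paste0(grid$species, "_", grid$stage, "_rep", grid$rep)
  m <- matrix(0L, nrow = n_orthologues, ncol = length(samples),
              dimnames = list(seq_len(n_orthologues), samples))
  owner <- if (structure == "species")
    sample(species, n_orthologues, replace = TRUE)
  else sample(stages, n_orthologues, replace = TRUE)
  on <- if (structure == "species")
    outer(owner, grid$species, `==`) else outer(owner, grid$stage, `==`)
  flip <- matrix(runif(length(m)) < noise, nrow = nrow(m))
  m[] <- as.integer(xor(on, flip))
  list(matrix = m,
       sample_species = setNames(grid$species, samples),
       sample_stage = setNames(grid$stage, samples))
}
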