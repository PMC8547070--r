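# exon-table builder from a compact spec: list(tx = list(gene, chrom, strand,
# exons = list(c(start, end), ...)))
tx_set <- function(...) {
  specs <- list(...)
  rows <- lapply(names(specs), function(id) {
    s <- specs[[id]]
    ex <- do.call(rbind, s$exons)
    data.frame(transcript_id = id, gene_id = s$gene,
               chrom = s$chrom %||% "chr1", strand = s$strand %||% "+",
               start = ex[, 1], end = ex[, 2])
  })
  fruitsplice::exon_table(
    transcript_id = unlist(lapply(rows, `[[`, "transcript_id")),
    gene_id = unlist(lapply(rows, `[[`, "gene_id")),
    chrom = unlist(lapply(rows, `[[`, "chrom")),
    strand = unlist(lapply(rows, `[[`, "strand")),
    start = unlist(lapply(rows, `[[`, "start")),
    end = unlist(lapply(rows, `[[`, "end")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random multi-isoform gene for oracle comparisons: a base architecture plus
# isoforms derived by random local modifications
random_gene <- function(gene, max_iso = 5, max_exons = 8, chrom = "chr1") {
  n_ex <- sample(3:max_exons, 1)
  ex_len <- sample(80:300, n_ex, replace = TRUE)
  in_len <- sample(60:400, n_ex - 1, replace = TRUE)
  strand <- sample(c("+", "-"), 1)
  start <- integer(n_ex); end <- integer(n_ex); pos <- sample(1:1000, 1)
  for (j in seq_len(n_ex)) {
    start[j] <- pos; end[j] <- pos + ex_len[j] - 1L
    pos <- end[j] + (if (j < n_ex) in_len[j] else 0L) + 1L
  }
  base <- cbind(start, end)
  n_iso <- sample(2:max_iso, 1)
  isos <- list(base)
  for (i in seq_len(n_iso - 1)) {
    mod <- sample(c("ES", "IR", "A5", "A3", "none"), 1)
    ex <- base
    if (mod == "ES" && n_ex >= 3) {
      k <- sample(2:(n_ex - 1), 1); ex <- ex[-k, , drop = FALSE]
    } else if (mod == "IR") {
      k <- sample(seq_len(n_ex - 1), 1)
      ex[k, 2] <- ex[k + 1, 2]; ex <- ex[-(k + 1), , drop = FALSE]
    } else if (mod == "A5") {
      k <- sample(seq_len(n_ex - 1), 1)
      d <- sample(10:min(40, ex[k, 2] - ex[k, 1] - 10), 1)
      ex[k, 2] <- ex[k, 2] - d
    } else if (mod == "A3") {
      k <- sample(seq_len(n_ex - 1), 1)
      d <- sample(10:min(40, ex[k + 1, 2] - ex[k + 1, 1] - 10), 1)
      ex[k + 1, 1] <- ex[k + 1, 1] + d
    }
    isos[[length(isos) + 1]] <- ex
  }
  rows <- do.call(rbind, lapply(seq_along(isos), function(i)
    data.frame(transcript_id = paste0(gene, ".t", i), gene_id = gene,
               chrom = chrom, strand = strand,
               start = isos[[i]][, 1], end = isos[[i]][, 2])))
  rows <- unique(rows)
  # drop duplicate isoforms (same chain) to keep transcripts distinct
  validate <- fruitsplice::exon_table(rows$transcript_id, rows$gene_id,
                                      rows$chrom, rows$strand,
                                      rows$start, rows$end)
  validate
}

# ---- brute-force event oracle -------------------------------------------
# literal application of the event definitions to every transcript pair;
# returns the set of (type, c1, c2, c3, c4) signatures
oracle_event_set <- function(exons) {
  out <- character(0)
  for (g in unique(exons$gene_id)) {
    ge <- exons[exons$gene_id == g, ]
    strand <- ge$strand[1]
    txs <- lapply(split(ge, ge$transcript_id), function(t)
      cbind(t$start[order(t$start)], t$end[order(t$start)]))
    introns <- lapply(txs, function(ex) {
      if (nrow(ex) < 2) return(cbind(integer(0), integer(0)))
      cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L)
    })
    ids <- names(txs)
    for (a in ids) for (b in ids) {
      if (a == b) next
      exa <- txs[[a]]; ina <- introns[[a]]
      exb <- txs[[b]]; inb <- introns[[b]]
      # ES: consecutive introns in a, skip intron in b
      if (nrow(ina) >= 2) for (i in seq_len(nrow(ina) - 1)) {
        s1 <- ina[i, 1]; e1 <- ina[i, 2]; s2 <- ina[i + 1, 1]; e2 <- ina[i + 1, 2]
        if (any(inb[, 1] == s1 & inb[, 2] == e2))
          out <- c(out, paste("ES", s1, e1, s2, e2))
      }
      # IR: intron of a (with its flanks) spanned by an exact exon of b
      if (nrow(ina) >= 1) for (i in seq_len(nrow(ina))) {
        s <- ina[i, 1]; e <- ina[i, 2]
        aa <- exa[exa[, 2] == s - 1L, 1]; bb <- exa[exa[, 1] == e + 1L, 2]
        if (length(aa) == 1 && length(bb) == 1 &&
            any(exb[, 1] == aa & exb[, 2] == bb))
          out <- c(out, paste("IR", aa, s - 1L, e + 1L, bb))
      }
      # A5SS/A3SS: introns sharing one boundary, flanking exons overlapping
      if (nrow(ina) >= 1 && nrow(inb) >= 1)
        for (i in seq_len(nrow(ina))) for (j in seq_len(nrow(inb))) {
          sa <- ina[i, 1]; ea <- ina[i, 2]; sb <- inb[j, 1]; eb <- inb[j, 2]
          if (ea == eb && sa != sb) {
            # preceding exons must overlap
            pa <- exa[exa[, 2] == sa - 1L, 1]
            pb <- exb[exb[, 2] == sb - 1L, 1]
            lo <- max(pa, pb); hi <- min(sa, sb) - 1L
            if (length(pa) == 1 && length(pb) == 1 && lo <= hi) {
              tp <- if (strand == "+") "A5SS" else "A3SS"
              ss <- sort(c(sa, sb))
              out <- c(out, paste(tp, ss[1], ea, ss[2], ea))
            }
          }
          if (sa == sb && ea != eb) {
            na_ <- exa[exa[, 1] == ea + 1L, 2]
            nb_ <- exb[exb[, 1] == eb + 1L, 2]
            lo <- max(sa, sb) ; hi <- min(na_, nb_)
            if (length(na_) == 1 && length(nb_) == 1 &&
                max(ea, eb) + 1L <= min(na_, nb_)) {
              tp <- if (strand == "+") "A3SS" else "A5SS"
              ee <- sort(c(ea, eb))
              out <- c(out, paste(tp, sa, ee[1], sa, ee[2]))
            }
          }
        }
    }
  }
  sort(unique(out))
}

event_signatures <- function(events) {
  if (nrow(events) == 0) return(character(0))
  sort(unique(paste(events$type, events$c1, events$c2, events$c3, events$c4)))
}

small_bundle <- function(seed = 1, n_orthogroups = 10,
                         genes_per_species_extra = 2, ...) {
  cfg <- fruitsplice::simulation_config(
    n_orthogroups = n_orthogroups,
    genes_per_species_extra = genes_per_species_extra,
    seed = seed, ...)
  fruitsplice::simulate_dataset(cfg)
}

build_species <- function(bundle, sp) {
  d <- bundle$species_data[[sp]]
  fruitsplice::build_high_quality_transcriptome(
    d$assembled, d$reference, d$junctions, d$tpm, d$stage_columns)
}

validate_asm <- function(df) {
  fruitsplice::exon_table(df$transcript_id, df$gene_id, df$chrom, df$strand,
                          df$start, df$end)
}

junction_keys <- function(introns) {
  paste(introns$chrom, introns$start, introns$end, introns$strand)
}
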