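#' Extract flanking exon sequences at alternative splice junctions
#'
#' Each event is represented by the exonic sequence flanking its
#' representative junction(s): the retained intron for IR, the skipping
#' junction for ES, and both alternative junctions for A5SS/A3SS. Flanks are
#' collected by walking outward along the exon chain of a transcript
#' carrying the junction, up to \code{max_len} bp per side; events where
#' either side yields fewer than \code{min_len} bp at every representative
#' junction are excluded (and reported in the \code{excluded} attribute).
#' Sequences are reported in transcription orientation (reverse-complemented
#' on the minus strand): \code{seq_up} is the donor-side flank.
#'
#' @param events event table
#' @param transcriptome exon table the events were detected from
#' @param genome \code{DNAStringSet} named by chromosome
#' @param species species label attached to every flank record
#' @param min_len,max_len flank length bounds in bp (default 30-300)
#' @param all_junctions extract every junction of both forms instead of the
#'   representative ones
#' @return data.frame species, event_id, type, gene_id, chrom, strand,
#'   jstart, jend, seq_up, seq_down, len_up, len_down; attribute
#'   \code{excluded}: data.frame event_id, reason
#' @export
extract_flanks <- function(events, transcriptome, genome, species,
                           min_len = 30, max_len = 300,
                           all_junctions = FALSE) {
  introns <- transcript_introns(transcriptome)
  intron_tx <- split(introns$transcript_id,
                     junction_key(introns$chrom, introns$start, introns$end,
                                  introns$strand))
  exons_by_tx <- split(as.data.frame(transcriptome),
                       transcriptome$transcript_id)
  rows <- list(); excluded <- list()

  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    juncs <- representative_junctions(ev, all_junctions, exons_by_tx)
    got <- FALSE
    for (j in juncs) {
      jk <- junction_key(ev$chrom, j[1], j[2], ev$strand)
      carriers <- intersect(intron_tx[[jk]],
                            c(ev$inclusion[[1]], ev$exclusion[[1]]))
      if (!length(carriers)) carriers <- intron_tx[[jk]]
      if (!length(carriers)) next
      fl <- junction_flanks(exons_by_tx[[sort(carriers)[1]]], j[1], j[2],
                            genome, ev$chrom, ev$strand, max_len)
      if (is.null(fl)) next
      if (nchar(fl$up) < min_len || nchar(fl$down) < min_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = species, event_id = ev$event_id, type = ev$type,
        gene_id = ev$gene_id, chrom = ev$chrom, strand = ev$strand,
        jstart = j[1], jend = j[2],
        seq_up = fl$up, seq_down = fl$down,
        len_up = nchar(fl$up), len_down = nchar(fl$down),
        stringsAsFactors = FALSE)
      got <- TRUE
    }
    if (!got)
      excluded[[length(excluded) + 1L]] <- data.frame(
        event_id = ev$event_id,
        reason = "no junction with both flanks >= min_len")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), event_id = character(),
               type = character(), gene_id = character(),
               chrom = character(), strand = character(),
               jstart = integer(), jend = integer(),
               seq_up = character(), seq_down = character(),
               len_up = integer(), len_down = integer())
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(event_id = character(), reason = character())
  out
}

# representative junction list (intron start/end pairs) for an event
representative_junctions <- function(ev, all_junctions, exons_by_tx) {
  if (all_junctions) {
    txs <- unique(c(ev$inclusion[[1]], ev$exclusion[[1]]))
    js <- list()
    for (t in txs) {
      ex <- exons_by_tx[[t]]
      ex <- ex[order(ex$start), ]
      if (nrow(ex) >= 2)
        for (k in seq_len(nrow(ex) - 1))
          js[[length(js) + 1L]] <- c(ex$end[k] + 1L, ex$start[k + 1] - 1L)
    }
    return(unique(js))
  }
  switch(ev$type,
    IR = list(c(ev$c2 + 1L, ev$c3 - 1L)),
    ES = list(c(ev$c1, ev$c4)),
    A5SS = ,
    A3SS = list(c(ev$c1, ev$c2), c(ev$c3, ev$c4)))
}

# exonic flanks of intron (s, e) along one transcript's exon chain,
# oriented by transcription strand
junction_flanks <- function(ex, s, e, genome, chrom, strand, max_len) {
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
  if (s < 1 || e > length(genome[[chrom]]))
    stop("junction outside chromosome bounds: ", chrom, ":", s, "-", e)
  ex <- ex[order(ex$start), ]
  left <- ex[ex$end <= s - 1L, , drop = FALSE]
  right <- ex[ex$start >= e + 1L, , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) return(NULL)
  collect <- function(segs, from_right) {
    # segs ordered by start; walk from the junction outward
    ord <- if (from_right) rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
    acc <- character(0); total <- 0L
    for (k in ord) {
      seg <- as.character(Biostrings::subseq(genome[[chrom]],
                                             segs$start[k], segs$end[k]))
      acc <- if (from_right) c(seg, acc) else c(acc, seg)
      total <- total + nchar(seg)
      if (total >= max_len) break
    }
    seqc <- paste(acc, collapse = "")
    n <- nchar(seqc)
    if (from_right) substr(seqc, max(1L, n - max_len + 1L), n)
    else substr(seqc, 1L, min(n, max_len))
  }
  left_seq <- collect(left, from_right = TRUE)
  right_seq <- collect(right, from_right = FALSE)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  if (strand == "+") list(up = left_seq, down = right_seq)
  else list(up = rc(right_seq), down = rc(left_seq))
}

# local alignment identity over aligned columns
local_align <- function(s1, s2, match = 1, mismatch = -1,
                        gap_open = 2, gap_ext = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1), Biostrings::DNAString(s2),
    type = "local", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_ext)
  len <- nchar(as.character(Biostrings::pattern(aln)))
  list(identity = if (len > 0) Biostrings::pid(aln, type = "PID1") / 100 else 0,
       length = len)
}

#' Cross-species flank similarity within each AS type
#'
#' Flank records are grouped by AS type; within a type, every cross-species
#' pair is scored by local nucleotide alignment (default: match +1,
#' mismatch -1, gap open -2, gap extend -1). A flank pair matches when both
#' the donor-side and the acceptor-side flanks align with identity at least
#' \code{min_identity} over at least \code{min_len} aligned columns.
#' Precomputed external hits (e.g. translated-search results in BLAST
#' tabular form, one row per matching flank-record pair identified by
#' \code{species|event_id|junction}) can replace the built-in scorer via
#' \code{external_matches}.
#'
#' @param flanks data.frame from \code{\link{extract_flanks}} (rows from all
#'   species bound together)
#' @param min_identity,min_len match thresholds
#' @param match,mismatch,gap_open,gap_ext aligner scores (penalties positive)
#' @param external_matches optional data.frame with columns qseqid, sseqid
#'   (flank record ids \code{species|event_id|jstart-jend|side}); when given,
#'   a pair matches iff both its up and down records appear
#' @return data.frame of matching pairs: type, species_a, event_a, gene_a,
#'   species_b, event_b, gene_b, junction_a, junction_b, id_up, id_down
#' @export
pairwise_flank_similarity <- function(flanks, min_identity = 0.6,
                                      min_len = 100, match = 1, mismatch = -1,
                                      gap_open = 2, gap_ext = 1,
                                      external_matches = NULL) {
  out <- list()
  if (nrow(flanks) == 0) return(empty_matches())
  flanks$rec_id <- paste(flanks$species, flanks$event_id,
                         paste0(flanks$jstart, "-", flanks$jend), sep = "|")
  ext_keys <- if (!is.null(external_matches))
    paste(external_matches$qseqid, external_matches$sseqid) else NULL
  for (tp in unique(flanks$type)) {
    f <- flanks[flanks$type == tp, , drop = FALSE]
    n <- nrow(f)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (f$species[i] == f$species[j]) next
      if (!is.null(ext_keys)) {
        up_ok <- paste(paste0(f$rec_id[i], "|up"),
                       paste0(f$rec_id[j], "|up")) %in% ext_keys ||
                 paste(paste0(f$rec_id[j], "|up"),
                       paste0(f$rec_id[i], "|up")) %in% ext_keys
        if (!up_ok) next
        down_ok <- paste(paste0(f$rec_id[i], "|down"),
                         paste0(f$rec_id[j], "|down")) %in% ext_keys ||
                   paste(paste0(f$rec_id[j], "|down"),
                         paste0(f$rec_id[i], "|down")) %in% ext_keys
        if (!down_ok) next
        id_up <- NA_real_; id_down <- NA_real_
      } else {
        up <- local_align(f$seq_up[i], f$seq_up[j], match, mismatch,
                          gap_open, gap_ext)
        if (up$identity < min_identity || up$length < min_len) next
        down <- local_align(f$seq_down[i], f$seq_down[j], match, mismatch,
                            gap_open, gap_ext)
        if (down$identity < min_identity || down$length < min_len) next
        id_up <- up$identity; id_down <- down$identity
      }
      out[[length(out) + 1L]] <- data.frame(
        type = tp,
        species_a = f$species[i], event_a = f$event_id[i],
        gene_a = f$gene_id[i],
        species_b = f$species[j], event_b = f$event_id[j],
        gene_b = f$gene_id[j],
        junction_a = paste0(f$jstart[i], "-", f$jend[i]),
        junction_b = paste0(f$jstart[j], "-", f$jend[j]),
        id_up = id_up, id_down = id_down, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_matches())
  do.call(rbind, out)
}

empty_matches <- function() {
  data.frame(type = character(), species_a = character(),
             event_a = character(), gene_a = character(),
             species_b = character(), event_b = character(),
             gene_b = character(), junction_a = character(),
             junction_b = character(), id_up = numeric(),
             id_down = numeric())
}

#' Detect conserved AS events across species
#'
#' Two events from different species are linked when they are of the same
#' type, their genes share an orthogroup, and their flank pairs match (both
#' sides; for A5SS/A3SS a match at either alternative junction suffices —
#' already encoded in the match rows). Clusters are the connected components
#' of the link graph. An event is conserved when it has at least one
#' cross-species link.
#'
#' @param matches data.frame from \code{\link{pairwise_flank_similarity}}
#' @param orthogroups named list og_id -> list(species -> gene ids)
#' @param species full species set (ordering of the counts matrix)
#' @param types AS type ordering of the counts matrix
#' @param verbose log skipped pairs
#' @return list(clusters, links, counts, summary) where clusters is a
#'   data.frame (cluster_id, species, gene_id, event_id, type,
#'   highly_conserved), counts the species x type matrix of conserved event
#'   counts and summary its percentage table
#'   (\code{\link{summarize_conserved_counts}})
#' @export
detect_conserved <- function(matches, orthogroups, species,
                             types = c("IR", "A3SS", "A5SS", "ES"),
                             verbose = FALSE) {
  gene_og <- list()
  for (og in names(orthogroups))
    for (g in unlist(orthogroups[[og]], use.names = FALSE))
      gene_og[[g]] <- c(gene_og[[g]], og)
  co_og <- function(a, b) {
    oa <- gene_og[[a]]; ob <- gene_og[[b]]
    !is.null(oa) && !is.null(ob) && length(intersect(oa, ob)) > 0
  }
  links <- matches[rep(FALSE, nrow(matches)), , drop = FALSE]
  if (nrow(matches)) {
    keep <- logical(nrow(matches))
    for (k in seq_len(nrow(matches))) {
      ga <- matches$gene_a[k]; gb <- matches$gene_b[k]
      if (is.null(gene_og[[ga]]) || is.null(gene_og[[gb]])) {
        msg("conserved: gene without orthogroup skipped (",
            ga, " / ", gb, ")", verbose = verbose)
        next
      }
      keep[k] <- co_og(ga, gb)
    }
    links <- matches[keep, , drop = FALSE]
  }
  # connected components over linked events
  node <- function(sp, ev) paste(sp, ev, sep = "|")
  nodes <- unique(c(node(links$species_a, links$event_a),
                    node(links$species_b, links$event_b)))
  clusters <- data.frame(cluster_id = integer(), species = character(),
                         gene_id = character(), event_id = character(),
                         type = character(), highly_conserved = logical())
  if (length(nodes)) {
    parent <- setNames(nodes, nodes)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (k in seq_len(nrow(links)))
      parent[[find(node(links$species_a[k], links$event_a[k]))]] <-
        find(node(links$species_b[k], links$event_b[k]))
    roots <- vapply(nodes, find, "")
    meta <- rbind(
      data.frame(node = node(links$species_a, links$event_a),
                 species = links$species_a, event_id = links$event_a,
                 gene_id = links$gene_a, type = links$type),
      data.frame(node = node(links$species_b, links$event_b),
                 species = links$species_b, event_id = links$event_b,
                 gene_id = links$gene_b, type = links$type))
    meta <- meta[!duplicated(meta$node), ]
    comp_list <- split(nodes, roots)
    comp_list <- comp_list[order(vapply(comp_list, min, ""))]
    cl <- lapply(seq_along(comp_list), function(ci) {
      m <- meta[match(comp_list[[ci]], meta$node), ]
      data.frame(cluster_id = ci, species = m$species, gene_id = m$gene_id,
                 event_id = m$event_id, type = m$type,
                 highly_conserved = length(unique(m$species)) ==
                   length(species))
    })
    clusters <- do.call(rbind, cl)
    clusters <- clusters[order(clusters$cluster_id, clusters$species,
                               clusters$event_id), ]
    rownames(clusters) <- NULL
  }
  counts <- matrix(0L, nrow = length(species), ncol = length(types),
                   dimnames = list(species, types))
  if (nrow(clusters)) {
    tb <- table(factor(clusters$species, levels = species),
                factor(clusters$type, levels = types))
    counts[] <- as.integer(tb)
  }
  list(clusters = clusters, links = links, counts = counts,
       summary = summarize_conserved_counts(counts))
}

#' Summarize a conserved-event counts matrix
#'
#' Adds per-species row totals with percentages of the grand total, and a
#' per-type totals row with type percentages. Percentages are reported to
#' two decimals with largest-remainder rounding, so each percentage set sums
#' to exactly 100.
#'
#' @param counts species x type integer matrix
#' @return list(table = data.frame with an "All" row, species_pct, type_pct,
#'   grand_total)
#' @export
summarize_conserved_counts <- function(counts) {
  counts <- as.matrix(counts)
  grand <- sum(counts)
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  pct <- function(x) {
    if (grand == 0) return(rep(NA_real_, length(x)))
    share <- 100 * x / grand
    base <- floor(share * 100) / 100
    units <- as.integer(round((100 - sum(base)) * 100))
    rem <- share - base
    top <- order(-rem, seq_along(rem))[seq_len(max(0, units))]
    base[top] <- base[top] + 0.01
    round(base, 2)
  }
  tab <- data.frame(species = rownames(counts), counts,
                    total = row_tot, pct = pct(row_tot),
                    check.names = FALSE, row.names = NULL)
  all_row <- data.frame(species = "All", t(col_tot), total = grand,
                        pct = if (grand > 0) 100 else NA_real_,
                        check.names = FALSE)
  list(table = rbind(tab, all_row),
       species_pct = setNames(pct(row_tot), rownames(counts)),
       type_pct = setNames(pct(col_tot), colnames(counts)),
       grand_total = grand)
}

#' Highly conserved clusters
#'
#' A cluster is highly conserved when its members span the full species set.
#'
#' @param clusters cluster data.frame from \code{\link{detect_conserved}}
#' @param species full species set
#' @return subset of \code{clusters} (all members of qualifying clusters)
#' @export
call_highly_conserved <- function(clusters, species) {
  if (nrow(clusters) == 0) return(clusters)
  sp_by_cl <- tapply(clusters$species, clusters$cluster_id,
                     function(x) length(unique(x)))
  keep <- as.integer(names(sp_by_cl)[sp_by_cl == length(species)])
  out <- clusters[clusters$cluster_id %in% keep, , drop = FALSE]
  out$highly_conserved <- rep(TRUE, nrow(out))
  out
}

#' Stage-wise PSI contrast for conserved vs nonconserved events
#'
#' For the conserved and the nonconserved event sets separately, compares
#' the immature-stage against the ripe-stage PSI values (pooled across
#' species) with the Wilcoxon rank-sum test.
#'
#' @param stage_psi_by_species named list species -> events x stages matrix
#' @param conserved_by_species named list species -> conserved event ids
#' @param stages the two stage names
#' @return list(conserved = list(immature, ripe, test) or NULL,
#'   nonconserved = list(immature, ripe, test))
#' @export
conserved_psi_contrast <- function(stage_psi_by_species, conserved_by_species,
                                   stages = c("immature", "ripe")) {
  pull <- function(conserved) {
    vals <- lapply(names(stage_psi_by_species), function(sp) {
      m <- stage_psi_by_species[[sp]]
      ids <- conserved_by_species[[sp]] %||% character(0)
      sel <- if (conserved) rownames(m) %in% ids else !rownames(m) %in% ids
      m[sel, , drop = FALSE]
    })
    m <- do.call(rbind, vals)
    list(immature = m[, stages[1]][!is.na(m[, stages[1]])],
         ripe = m[, stages[2]][!is.na(m[, stages[2]])])
  }
  run <- function(s) {
    if (!length(s$immature) || !length(s$ripe)) return(NULL)
    c(s, list(test = wilcoxon_rank_sum(s$immature, s$ripe)))
  }
  cons <- run(pull(TRUE))
  if (is.null(cons))
    warning("no conserved events with PSI values; conserved contrast omitted")
  list(conserved = cons, nonconserved = run(pull(FALSE)))
}
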