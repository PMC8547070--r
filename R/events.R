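#' Detect local alternative splicing events from a transcriptome
#'
#' Pairwise comparison of exon chains within each gene yields the four local
#' event types:
#' \describe{
#'   \item{ES}{a cassette exon with both flanking introns in one form and a
#'     single skipping intron (same outer boundaries) in the other;}
#'   \item{IR}{an intron in one form spanned by a continuous exon in the
#'     other, with exactly matching outer exon boundaries;}
#'   \item{A5SS/A3SS}{two introns sharing one boundary and differing at the
#'     other, with overlapping exons on the shared side; the variable
#'     boundary is labelled donor (5') or acceptor (3') relative to the
#'     transcription direction.}
#' }
#' Events are deduplicated by (type, coordinates). Inclusion/exclusion sets
#' contain every transcript of the gene compatible with the respective form;
#' the inclusion convention is: ES = exon included, IR = intron retained,
#' A5SS/A3SS = the form producing the longer exon (the shorter intron).
#'
#' @param transcriptome exon table
#' @return data.frame with columns event_id, type, gene_id, chrom, strand,
#'   c1..c4 (type-specific junction boundaries) and list columns
#'   inclusion, exclusion (character vectors of transcript ids)
#' @export
detect_events <- function(transcriptome) {
  genes <- split(as.data.frame(transcriptome), transcriptome$gene_id)
  out <- lapply(genes, detect_events_gene)
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) res <- empty_events()
  rownames(res) <- NULL
  res
}

empty_events <- function() {
  data.frame(event_id = character(), type = character(),
             gene_id = character(), chrom = character(), strand = character(),
             c1 = integer(), c2 = integer(), c3 = integer(), c4 = integer(),
             inclusion = I(list()), exclusion = I(list()))
}

event_id_string <- function(gene, type, chrom, c1, c2, c3, c4, strand) {
  sprintf("%s;%s:%s:%d-%d:%d-%d:%s", gene, type, chrom, c1, c2, c3, c4, strand)
}

detect_events_gene <- function(g) {
  tx_ids <- unique(g$transcript_id)
  if (length(tx_ids) < 2) return(NULL)
  if (length(unique(g$strand)) != 1)
    stop("gene ", g$gene_id[1], " has transcripts on both strands")
  chrom <- g$chrom[1]; strand <- g$strand[1]; gene <- g$gene_id[1]
  ex_by_tx <- lapply(split(g, g$transcript_id), function(t)
    cbind(start = t$start[order(t$start)], end = t$end[order(t$start)]))
  ex_by_tx <- ex_by_tx[tx_ids]

  # per-transcript intron records with flanking exon info
  intron_recs <- list()
  exon_key_tx <- list()   # "s:e" exact exon -> tx set
  intron_key_tx <- list() # "s:e" intron -> tx set
  for (t in tx_ids) {
    ex <- ex_by_tx[[t]]
    n <- nrow(ex)
    for (i in seq_len(n)) {
      k <- paste0(ex[i, 1], ":", ex[i, 2])
      exon_key_tx[[k]] <- c(exon_key_tx[[k]], t)
    }
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        s <- ex[i, 2] + 1L; e <- ex[i + 1, 1] - 1L
        k <- paste0(s, ":", e)
        intron_key_tx[[k]] <- c(intron_key_tx[[k]], t)
        intron_recs[[length(intron_recs) + 1L]] <- list(
          tx = t, s = s, e = e,
          prev_start = ex[i, 1], next_end = ex[i + 1, 2])
      }
    }
  }
  if (!length(intron_recs)) return(NULL)
  irec <- data.frame(
    tx = vapply(intron_recs, `[[`, "", "tx"),
    s = vapply(intron_recs, function(x) as.integer(x$s), 1L),
    e = vapply(intron_recs, function(x) as.integer(x$e), 1L),
    prev_start = vapply(intron_recs, function(x) as.integer(x$prev_start), 1L),
    next_end = vapply(intron_recs, function(x) as.integer(x$next_end), 1L),
    stringsAsFactors = FALSE)

  events <- list()
  add_event <- function(type, c1, c2, c3, c4, inclusion, exclusion) {
    inclusion <- sort(unique(inclusion))
    exclusion <- sort(unique(exclusion))
    if (!length(inclusion) || !length(exclusion)) return(invisible(NULL))
    id <- event_id_string(gene, type, chrom, c1, c2, c3, c4, strand)
    if (is.null(events[[id]])) {
      events[[id]] <<- data.frame(
        event_id = id, type = type, gene_id = gene, chrom = chrom,
        strand = strand, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
        inclusion = I(list(inclusion)), exclusion = I(list(exclusion)))
    }
    invisible(NULL)
  }

  ## --- exon skipping ---------------------------------------------------
  # consecutive intron pairs (i, i+1) of one transcript vs skip intron
  for (t in tx_ids) {
    rt <- irec[irec$tx == t, , drop = FALSE]
    if (nrow(rt) < 2) next
    rt <- rt[order(rt$s), , drop = FALSE]
    for (i in seq_len(nrow(rt) - 1)) {
      s1 <- rt$s[i]; e1 <- rt$e[i]
      s2 <- rt$s[i + 1]; e2 <- rt$e[i + 1]
      skip_tx <- intron_key_tx[[paste0(s1, ":", e2)]]
      if (is.null(skip_tx)) next
      cass <- paste0(e1 + 1L, ":", s2 - 1L)
      incl <- intersect(intersect(intron_key_tx[[paste0(s1, ":", e1)]],
                                  intron_key_tx[[paste0(s2, ":", e2)]]),
                        exon_key_tx[[cass]])
      add_event("ES", s1, e1, s2, e2, incl, setdiff(skip_tx, incl))
    }
  }

  ## --- intron retention -------------------------------------------------
  # intron (s,e) with its own flanking exons (a, s-1) and (e+1, b) vs an
  # exact continuous exon (a, b)
  ir_groups <- split(irec, paste(irec$s, irec$e, irec$prev_start,
                                 irec$next_end))
  for (grp in ir_groups) {
    s <- grp$s[1]; e <- grp$e[1]; a <- grp$prev_start[1]; b <- grp$next_end[1]
    retained <- exon_key_tx[[paste0(a, ":", b)]]
    if (is.null(retained)) next
    add_event("IR", a, s - 1L, e + 1L, b, retained, unique(grp$tx))
  }

  ## --- alternative 5'/3' splice sites -----------------------------------
  uintr <- unique(irec[, c("s", "e")])
  # shared end, differing start (variable donor on +, acceptor on -)
  for (e in unique(uintr$e)) {
    ss <- sort(unique(uintr$s[uintr$e == e]))
    if (length(ss) < 2) next
    for (i in seq_len(length(ss) - 1)) for (j in seq(i + 1, length(ss))) {
      s1 <- ss[i]; s2 <- ss[j] # s1 < s2; shorter intron = (s2, e)
      # preceding exons must overlap: the long-exon form's exon [a2, s2-1]
      # must reach back to [a1, s1-1]
      r1 <- irec[irec$s == s1 & irec$e == e, , drop = FALSE]
      r2 <- irec[irec$s == s2 & irec$e == e, , drop = FALSE]
      if (!any(outer(r2$prev_start, s1 - 1L, `<=`))) next
      type <- if (strand == "+") "A5SS" else "A3SS"
      add_event(type, s1, e, s2, e,
                inclusion = unique(r2$tx), exclusion = unique(r1$tx))
    }
  }
  # shared start, differing end (variable acceptor on +, donor on -)
  for (s in unique(uintr$s)) {
    ee <- sort(unique(uintr$e[uintr$s == s]))
    if (length(ee) < 2) next
    for (i in seq_len(length(ee) - 1)) for (j in seq(i + 1, length(ee))) {
      e1 <- ee[i]; e2 <- ee[j] # e1 < e2; shorter intron = (s, e1)
      r1 <- irec[irec$s == s & irec$e == e1, , drop = FALSE]
      r2 <- irec[irec$s == s & irec$e == e2, , drop = FALSE]
      # following exons must overlap: [e1+1, b1] and [e2+1, b2]
      if (!any(outer(r1$next_end, e2 + 1L, `>=`))) next
      type <- if (strand == "+") "A3SS" else "A5SS"
      add_event(type, s, e1, s, e2,
                inclusion = unique(r1$tx), exclusion = unique(r2$tx))
    }
  }

  if (!length(events)) return(NULL)
  do.call(rbind, events)
}
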