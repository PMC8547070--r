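#' Classify assembled transcripts against a reference annotation
#'
#' Assigns a structural class code to every assembled transcript:
#' \itemize{
#'   \item \code{"="} intron chain identical to a reference transcript
#'     (exact exon coordinates for single-exon transcripts);
#'   \item \code{"x"} exonic overlap with a reference exon on the opposite
#'     strand;
#'   \item \code{"s"} exonic overlap of a reference intron on the opposite
#'     strand;
#'   \item \code{"o"} any other same-strand overlap with a reference gene;
#'   \item \code{"u"} no overlap with any reference gene on either strand.
#' }
#' Precedence: \code{= > x > s > o > u}.
#'
#' @param assembled,reference exon tables
#' @return named character vector, one code per assembled transcript
#' @export
classify_vs_reference <- function(assembled, reference) {
  tx <- unique(assembled$transcript_id)
  if (length(tx) == 0) return(setNames(character(0), character(0)))
  if (any(!tx %in% assembled$transcript_id))
    stop("transcript with empty exon list")

  ref_sig <- unique(chain_signature(reference))
  asm_sig <- chain_signature(assembled)

  asm_gr <- GenomicRanges::GRanges(assembled$chrom,
    IRanges::IRanges(assembled$start, assembled$end))
  ref_ex_gr <- GenomicRanges::GRanges(reference$chrom,
    IRanges::IRanges(reference$start, reference$end))
  ref_in <- transcript_introns(reference)
  ref_in_gr <- GenomicRanges::GRanges(ref_in$chrom,
    IRanges::IRanges(ref_in$start, ref_in$end))
  # reference gene spans (for the same-strand "o" bucket)
  ref_span <- do.call(rbind, lapply(split(reference, reference$gene_id),
    function(g) data.frame(chrom = g$chrom[1], strand = g$strand[1],
                           start = min(g$start), end = max(g$end))))
  ref_sp_gr <- GenomicRanges::GRanges(ref_span$chrom,
    IRanges::IRanges(ref_span$start, ref_span$end))

  ov_ex <- GenomicRanges::findOverlaps(asm_gr, ref_ex_gr, ignore.strand = TRUE)
  ov_in <- GenomicRanges::findOverlaps(asm_gr, ref_in_gr, ignore.strand = TRUE)
  ov_sp <- GenomicRanges::findOverlaps(asm_gr, ref_sp_gr, ignore.strand = TRUE)

  strand_of <- function(hits, ref_strand) {
    # per (assembled exon row, hit) whether strands agree
    ref_strand[S4Vectors::subjectHits(hits)] ==
      assembled$strand[S4Vectors::queryHits(hits)]
  }
  per_tx_any <- function(hits, keep) {
    rows <- S4Vectors::queryHits(hits)[keep]
    unique(assembled$transcript_id[rows])
  }

  same_ex <- per_tx_any(ov_ex, strand_of(ov_ex, reference$strand))
  opp_ex  <- per_tx_any(ov_ex, !strand_of(ov_ex, reference$strand))
  opp_in  <- per_tx_any(ov_in, !strand_of(ov_in, ref_in$strand))
  same_sp <- per_tx_any(ov_sp, strand_of(ov_sp, ref_span$strand))

  code <- setNames(rep("u", length(tx)), tx)
  code[tx %in% same_sp | tx %in% same_ex] <- "o"
  code[tx %in% opp_in] <- "s"
  code[tx %in% opp_ex] <- "x"
  code[asm_sig[tx] %in% ref_sig] <- "="
  code
}

#' Junctions of assembled transcripts absent from the reference
#'
#' A junction is novel iff its (chrom, intron start, intron end, strand)
#' tuple equals no reference intron; matching is strand-sensitive.
#'
#' @param assembled,reference exon tables
#' @return data.frame chrom, start, end, strand (unique novel junctions)
#' @export
novel_junctions <- function(assembled, reference) {
  ai <- transcript_introns(assembled)
  ri <- transcript_introns(reference)
  ak <- junction_key(ai$chrom, ai$start, ai$end, ai$strand)
  rk <- junction_key(ri$chrom, ri$start, ri$end, ri$strand)
  nov <- ai[!ak %in% rk, c("chrom", "start", "end", "strand")]
  unique(nov)
}

# KEEP rule for one novel junction given two replicate read counts
junction_supported <- function(c1, c2, min_both = 4, min_single = 10) {
  (c1 >= min_both & c2 >= min_both) | (c1 >= min_single | c2 >= min_single)
}

#' Remove transcripts with poorly supported novel junctions
#'
#' A novel junction is supported when it has at least 4 reads in both
#' replicates, or at least 10 reads in one replicate. A transcript survives
#' iff every novel junction it contains is supported. Junctions missing from
#' the support table count as zero reads in all replicates.
#'
#' @param transcripts exon table
#' @param novel data.frame of novel junctions (chrom, start, end, strand)
#' @param support data.frame chrom, start, end, strand, count_rep1, count_rep2
#' @param min_both,min_single support thresholds
#' @param ignore_strand match junctions ignoring strand (for unstranded
#'   junction tables)
#' @param verbose log removals
#' @return list(kept = exon table, removed = data.frame transcript_id, reason)
#' @export
filter_by_junction_support <- function(transcripts, novel, support,
                                       min_both = 4, min_single = 10,
                                       ignore_strand = FALSE, verbose = FALSE) {
  ti <- transcript_introns(transcripts)
  if (nrow(ti) == 0 || nrow(novel) == 0) {
    return(list(kept = transcripts,
                removed = data.frame(transcript_id = character(),
                                     reason = character())))
  }
  jkey <- function(df) {
    if (ignore_strand) junction_key(df$chrom, df$start, df$end, "*")
    else junction_key(df$chrom, df$start, df$end, df$strand)
  }
  nk <- jkey(novel)
  sk <- jkey(support)
  idx <- match(nk, sk)
  c1 <- ifelse(is.na(idx), 0, support$count_rep1[idx])
  c2 <- ifelse(is.na(idx), 0, support$count_rep2[idx])
  if (any(is.na(idx)))
    msg("junction filter: ", sum(is.na(idx)),
        " novel junction(s) absent from support table, counted as 0",
        verbose = verbose)
  bad <- nk[!junction_supported(c1, c2, min_both, min_single)]
  tik <- jkey(ti)
  bad_tx <- unique(ti$transcript_id[tik %in% bad])
  kept <- transcripts[!transcripts$transcript_id %in% bad_tx, , drop = FALSE]
  if (verbose && length(bad_tx))
    msg("JUNC removed: ", paste(bad_tx, collapse = ", "))
  list(kept = validate_exon_table(kept),
       removed = data.frame(transcript_id = bad_tx,
                            reason = rep("JUNC", length(bad_tx))))
}

#' Remove transcripts not expressed above 1 TPM in both replicates
#'
#' Strict inequality: a transcript survives iff TPM > threshold in both
#' replicate columns. Transcripts missing from the table count as 0 TPM.
#'
#' @param transcripts exon table
#' @param expr TPM matrix (transcripts x samples)
#' @param rep_cols the two replicate column names for the stage
#' @param tpm_min threshold (default 1)
#' @param verbose log removals
#' @return list(kept, removed)
#' @export
filter_by_expression <- function(transcripts, expr, rep_cols, tpm_min = 1,
                                 verbose = FALSE) {
  stopifnot(length(rep_cols) == 2, all(rep_cols %in% colnames(expr)))
  tx <- unique(transcripts$transcript_id)
  idx <- match(tx, rownames(expr))
  if (any(is.na(idx)))
    msg("expression filter: ", sum(is.na(idx)),
        " transcript(s) absent from TPM table, counted as 0", verbose = verbose)
  v1 <- ifelse(is.na(idx), 0, expr[ifelse(is.na(idx), 1, idx), rep_cols[1]])
  v2 <- ifelse(is.na(idx), 0, expr[ifelse(is.na(idx), 1, idx), rep_cols[2]])
  keep <- v1 > tpm_min & v2 > tpm_min
  bad_tx <- tx[!keep]
  kept <- transcripts[!transcripts$transcript_id %in% bad_tx, , drop = FALSE]
  if (verbose && length(bad_tx)) msg("TPM removed: ", paste(bad_tx, collapse = ", "))
  list(kept = validate_exon_table(kept),
       removed = data.frame(transcript_id = bad_tx,
                            reason = rep("TPM", length(bad_tx))))
}

#' Remove transcripts classified as novel or antisense genes
#'
#' Drops class codes "u", "x" and "s".
#'
#' @param transcripts exon table
#' @param class_codes named vector from \code{\link{classify_vs_reference}}
#' @param drop codes to remove
#' @return list(kept, removed)
#' @export
filter_by_class_code <- function(transcripts, class_codes,
                                 drop = c("u", "x", "s")) {
  tx <- unique(transcripts$transcript_id)
  bad_tx <- tx[class_codes[tx] %in% drop]
  kept <- transcripts[!transcripts$transcript_id %in% bad_tx, , drop = FALSE]
  list(kept = validate_exon_table(kept),
       removed = data.frame(transcript_id = bad_tx,
                            reason = rep("CLASS", length(bad_tx))))
}

#' Remove single-exon transcripts not present in the reference
#'
#' A single-exon transcript survives only if the reference contains a
#' single-exon transcript with identical (chrom, strand, start, end).
#' Multi-exon transcripts are untouched.
#'
#' @param transcripts exon table
#' @param reference exon table
#' @return list(kept, removed)
#' @export
filter_single_exon <- function(transcripts, reference) {
  nx <- n_exons(transcripts)
  mono <- names(nx)[nx == 1L]
  if (!length(mono)) {
    return(list(kept = transcripts,
                removed = data.frame(transcript_id = character(),
                                     reason = character())))
  }
  rnx <- n_exons(reference)
  rmono <- reference[reference$transcript_id %in% names(rnx)[rnx == 1L], ]
  rkey <- paste(rmono$chrom, rmono$strand, rmono$start, rmono$end)
  m <- transcripts[transcripts$transcript_id %in% mono, ]
  mkey <- paste(m$chrom, m$strand, m$start, m$end)
  bad_tx <- m$transcript_id[!mkey %in% rkey]
  kept <- transcripts[!transcripts$transcript_id %in% bad_tx, , drop = FALSE]
  list(kept = validate_exon_table(kept),
       removed = data.frame(transcript_id = bad_tx,
                            reason = rep("MONO", length(bad_tx))))
}

#' Merge per-stage transcript sets, keeping the longer transcript
#'
#' Transcripts are grouped by (chrom, strand, ordered intron chain);
#' single-exon transcripts by exact coordinates. Within a group the
#' transcript with the greatest summed exon length is kept (ties broken by
#' transcript id, lexicographically), so stage variants of the same intron
#' chain collapse to the longer model.
#'
#' @param stage_sets list of exon tables (one per stage)
#' @return merged exon table
#' @export
merge_stages <- function(stage_sets) {
  all_tx <- do.call(rbind, lapply(stage_sets, as.data.frame))
  if (is.null(all_tx) || nrow(all_tx) == 0)
    return(exon_table(character(0), character(0), character(0),
                      character(0), integer(0), integer(0)))
  # a transcript id present in several stages with identical structure is one
  # model; disambiguate duplicated ids pointing at different structures
  all_tx <- unique(all_tx[, c("transcript_id", "gene_id", "chrom", "strand",
                              "start", "end")])
  sig <- chain_signature(validate_exon_table(all_tx))
  len <- transcript_lengths(all_tx)
  tx <- names(sig)
  ord <- order(sig[tx], -len[tx], tx)
  winners <- tx[ord][!duplicated(sig[tx][ord])]
  validate_exon_table(all_tx[all_tx$transcript_id %in% winners, , drop = FALSE])
}

#' Build the high-quality transcriptome for one species
#'
#' Applies, per stage, the filter cascade (novel-junction read support,
#' expression above 1 TPM in both replicates, removal of novel/antisense
#' class codes, removal of unmatched single-exon transcripts) and then
#' merges the stages keeping the longer transcript per intron chain.
#'
#' @param assembled named list stage -> exon table of assembled transcripts
#' @param reference exon table of the reference annotation
#' @param junctions named list stage -> junction support data.frame
#' @param expr TPM matrix
#' @param stage_columns named list stage -> the two replicate column names
#' @param tpm_min,min_both,min_single thresholds
#' @param verbose log removals
#' @return list(transcriptome, summary, removals, expressed_genes)
#' @export
build_high_quality_transcriptome <- function(assembled, reference, junctions,
                                             expr, stage_columns,
                                             tpm_min = 1, min_both = 4,
                                             min_single = 10, verbose = FALSE) {
  stages <- names(assembled)
  stopifnot(!is.null(stages), all(stages %in% names(junctions)),
            all(stages %in% names(stage_columns)))
  summary_rows <- list()
  removals <- list()
  filtered <- list()
  for (st in stages) {
    cur <- assembled[[st]]
    codes <- classify_vs_reference(cur, reference)
    nov <- novel_junctions(cur, reference)
    steps <- list(
      junction_support = function(x)
        filter_by_junction_support(x, nov, junctions[[st]],
                                   min_both = min_both,
                                   min_single = min_single, verbose = verbose),
      expression = function(x)
        filter_by_expression(x, expr, stage_columns[[st]],
                             tpm_min = tpm_min, verbose = verbose),
      class_code = function(x) filter_by_class_code(x, codes),
      single_exon = function(x) filter_single_exon(x, reference)
    )
    for (step in names(steps)) {
      n_before <- length(unique(cur$transcript_id))
      res <- steps[[step]](cur)
      cur <- res$kept
      n_after <- length(unique(cur$transcript_id))
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        stage = st, filter_step = step,
        n_before = n_before, n_after = n_after)
      if (nrow(res$removed))
        removals[[length(removals) + 1L]] <-
          cbind(stage = st, res$removed)
    }
    filtered[[st]] <- cur
  }
  merged <- merge_stages(filtered)
  summary_rows[[length(summary_rows) + 1L]] <- data.frame(
    stage = "merged", filter_step = "merge_stages",
    n_before = sum(vapply(filtered, function(x)
      length(unique(x$transcript_id)), 1L)),
    n_after = length(unique(merged$transcript_id)))
  removed <- if (length(removals)) do.call(rbind, removals) else
    data.frame(stage = character(), transcript_id = character(),
               reason = character())
  list(transcriptome = merged,
       summary = do.call(rbind, summary_rows),
       removals = removed,
       expressed_genes = length(unique(merged$gene_id)))
}
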