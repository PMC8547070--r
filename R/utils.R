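#' @keywords internal
"_PACKAGE"

#' @importFrom stats fisher.test wilcox.test rnorm runif rbinom rpois qlogis
#'   plogis setNames aggregate cor as.dist hclust cutree complete.cases
#' @importFrom utils read.delim write.table
NULL

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an exon table
#'
#' The package-wide transcript representation: one row per exon, 1-based
#' inclusive coordinates, exons sorted by start within each transcript.
#'
#' @param transcript_id,gene_id,chrom,strand,start,end vectors of equal length
#' @return a data.frame of class \code{exon_df}
#' @export
exon_table <- function(transcript_id, gene_id, chrom, strand, start, end) {
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  validate_exon_table(df)
}

validate_exon_table <- function(df) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand",
                  "start", "end") %in% names(df)))
  if (nrow(df) == 0) {
    class(df) <- c("exon_df", "data.frame")
    return(df)
  }
  if (any(df$end < df$start)) stop("exon with end < start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  # exons within a transcript must not overlap
  by_tx <- split(seq_len(nrow(df)), df$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      s <- df$start[idx]; e <- df$end[idx]
      if (any(s[-1] <= e[-length(e)]))
        stop("overlapping exons in transcript ", df$transcript_id[idx[1]])
    }
  }
  class(df) <- unique(c("exon_df", class(df)))
  df
}

#' Introns of every transcript
#'
#' @param exons an exon table
#' @return data.frame transcript_id, gene_id, chrom, strand, start, end where
#'   start is the first intronic base and end the last (1-based inclusive)
#' @export
transcript_introns <- function(exons) {
  if (nrow(exons) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer()))
  }
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  n <- nrow(exons)
  same <- exons$transcript_id[-n] == exons$transcript_id[-1]
  i <- which(same)
  data.frame(
    transcript_id = exons$transcript_id[i],
    gene_id = exons$gene_id[i],
    chrom = exons$chrom[i],
    strand = exons$strand[i],
    start = exons$end[i] + 1L,
    end = exons$start[i + 1L] - 1L,
    stringsAsFactors = FALSE
  )
}

junction_key <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

# ordered intron-chain signature per transcript (multi-exon), or exact exon
# coordinates for single-exon transcripts
chain_signature <- function(exons) {
  introns <- transcript_introns(exons)
  tx <- unique(exons$transcript_id)
  sig <- setNames(character(length(tx)), tx)
  if (nrow(introns) > 0) {
    ik <- split(paste0(introns$start, "-", introns$end),
                introns$transcript_id)
    meta <- introns[!duplicated(introns$transcript_id), ]
    for (t in names(ik)) sig[t] <- paste0("J|", meta$chrom[match(t, meta$transcript_id)],
                                          ":", meta$strand[match(t, meta$transcript_id)],
                                          "|", paste(ik[[t]], collapse = ","))
  }
  mono <- setdiff(tx, names(which(sig != "")))
  if (length(mono)) {
    m <- exons[exons$transcript_id %in% mono, ]
    sig[m$transcript_id] <- paste0("M|", m$chrom, ":", m$strand, "|",
                                   m$start, "-", m$end)
  }
  sig
}

# total exonic length per transcript
transcript_lengths <- function(exons) {
  len <- tapply(exons$end - exons$start + 1L, exons$transcript_id, sum)
  setNames(as.integer(len), names(len))
}

n_exons <- function(exons) {
  setNames(as.integer(table(exons$transcript_id)),
           names(table(exons$transcript_id)))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
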