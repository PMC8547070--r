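#' Read transcript models from a GTF file
#'
#' Exon records are read through \pkg{rtracklayer}; 1-based inclusive
#' coordinates are kept as-is.
#'
#' @param path GTF file
#' @return an exon table (see \code{\link{exon_table}})
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  exon_table(
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    gene_id = S4Vectors::mcols(gr)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Write transcript models to a GTF file
#'
#' @param exons an exon table
#' @param path output file
#' @export
write_gtf <- function(exons, path) {
  # records written directly (1-based inclusive, exon features only) so that
  # output is byte-reproducible; deterministic record order
  exons <- exons[order(exons$chrom, exons$gene_id, exons$transcript_id,
                       exons$start), , drop = FALSE]
  lines <- sprintf(
    "%s\tfruitsplice\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$chrom, exons$start, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcript-level TPM table
#'
#' @param path TSV with a transcript_id column and one column per sample
#' @return matrix (transcripts x samples)
#' @export
read_tpm <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a junction read-support table
#'
#' @param path TSV with columns chrom, start, end, strand, count_rep1,
#'   count_rep2 (start/end = first/last intronic base, 1-based)
#' @return data.frame
#' @export
read_junctions <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  df
}

#' Read an orthogroup membership table
#'
#' Tab-separated, first column the orthogroup id, one column per species with
#' comma-separated gene ids (empty when the species has no member).
#'
#' @param path TSV file
#' @return named list og_id -> list(species -> character vector of genes)
#' @export
read_orthogroups <- function(path) {
  df <- read_tsv(path)
  species <- names(df)[-1]
  out <- lapply(seq_len(nrow(df)), function(i) {
    members <- lapply(species, function(sp) {
      v <- df[[sp]][i]
      if (is.na(v) || v == "") character(0)
      else trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    })
    names(members) <- species
    members[vapply(members, length, 1L) > 0]
  })
  names(out) <- df[[1]]
  out
}

#' Write an orthogroup table
#' @param orthogroups named list as returned by \code{read_orthogroups}
#' @param species species order for columns
#' @param path output TSV
#' @export
write_orthogroups <- function(orthogroups, species, path) {
  rows <- lapply(names(orthogroups), function(og) {
    m <- orthogroups[[og]]
    c(og, vapply(species, function(sp)
      paste(m[[sp]] %||% character(0), collapse = ","), ""))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("orthogroup_id", species)
  write_tsv(df, path)
}

#' Read BLAST tabular (-outfmt 6 dialect) similarity hits
#' @param path TSV without header: qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore
#' @return data.frame with those column names
#' @export
read_blast_hits <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")[seq_len(ncol(df))]
  df
}

#' Read genome sequences
#' @param path FASTA file, one record per chromosome
#' @return a \code{Biostrings::DNAStringSet}
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}
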