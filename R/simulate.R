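BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

mutate_dna <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(BASES, b), 1), "")
  }
  paste(v, collapse = "")
}

#' Simulation configuration
#'
#' Defines the synthetic study: a multi-species, two-stage, replicated
#' fruit-development design with planted AS events of all four types,
#' stage-biased PSI, conserved events across diverged orthologues and
#' assembly artefacts exercising every transcript filter.
#'
#' @param n_species number of species (>= 2)
#' @param species species names (defaults to the first \code{n_species} of
#'   cucumber, melon, papaya, peach, sp5, ...)
#' @param n_orthogroups number of orthogroups; every orthogroup has one gene
#'   per species and carries one planted AS event
#' @param genes_per_species_extra species-specific genes without orthologues
#' @param event_mix proportions over c(IR, ES, A3SS, A5SS), summing to 1
#' @param frac_conserved_events fraction of orthogroups whose event is
#'   planted at the same position in every species with conserved flanks
#' @param frac_stage_specific fraction of events with stage-specific
#'   occurrence (true PSI 0.5 at the "on" stage, 0.99 or 0.01 at the other)
#' @param flank_divergence per-species substitution rate applied to
#'   orthologous exonic sequence
#' @param frac_multicopy fraction of orthogroups with a duplicated gene per
#'   species (resolved by RBH + synteny evidence)
#' @param frac_minus_strand fraction of genes on the minus strand
#' @param n_stages number of stages (only 2 supported: immature, ripe)
#' @param n_replicates replicates per stage (>= 1)
#' @param tpm_depth abundance scale: per-gene total TPM ~ depth * U(0.5, 2)
#' @param psi_noise_sd replicate PSI jitter (logit scale)
#' @param frac_artifact_transcripts proportion of artefact transcripts
#'   relative to real assembled transcripts (flavours cycle over the four
#'   filters: low junction support, low TPM, antisense, unmatched
#'   single-exon)
#' @param n_artifacts_per_stage exact artefact count per stage (overrides
#'   the fraction when not NULL)
#' @param seed integer seed; identical seeds give byte-identical bundles
#' @return list of class \code{sim_config}
#' @export
simulation_config <- function(n_species = 4, species = NULL,
                              n_orthogroups = 40,
                              genes_per_species_extra = 5,
                              event_mix = c(IR = 0.25, ES = 0.25,
                                            A3SS = 0.25, A5SS = 0.25),
                              frac_conserved_events = 0.3,
                              frac_stage_specific = 0.2,
                              flank_divergence = 0.1,
                              frac_multicopy = 0.1,
                              frac_minus_strand = 0.3,
                              n_stages = 2, n_replicates = 2,
                              tpm_depth = 100, psi_noise_sd = 0.1,
                              frac_artifact_transcripts = 0.1,
                              n_artifacts_per_stage = NULL,
                              seed = 1) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (n_orthogroups < 1) stop("degenerate config: n_orthogroups must be >= 1")
  if (n_stages != 2) stop("only two stages (immature, ripe) are supported")
  props <- c(frac_conserved_events, frac_stage_specific, flank_divergence,
             frac_multicopy, frac_minus_strand, frac_artifact_transcripts)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (any(event_mix < 0) || abs(sum(event_mix) - 1) > 1e-8)
    stop("event_mix must be nonnegative and sum to 1")
  if (tpm_depth <= 0) stop("tpm_depth must be positive")
  if (is.null(species))
    species <- c("cucumber", "melon", "papaya", "peach",
                 paste0("sp", seq_len(max(0, n_species - 4)) + 4))[
                   seq_len(n_species)]
  stopifnot(length(species) == n_species)
  names(event_mix) <- names(event_mix) %||% c("IR", "ES", "A3SS", "A5SS")
  structure(list(
    n_species = n_species, species = species,
    n_orthogroups = n_orthogroups,
    genes_per_species_extra = genes_per_species_extra,
    event_mix = event_mix,
    frac_conserved_events = frac_conserved_events,
    frac_stage_specific = frac_stage_specific,
    flank_divergence = flank_divergence,
    frac_multicopy = frac_multicopy,
    frac_minus_strand = frac_minus_strand,
    n_stages = n_stages, n_replicates = n_replicates,
    tpm_depth = tpm_depth, psi_noise_sd = psi_noise_sd,
    frac_artifact_transcripts = frac_artifact_transcripts,
    n_artifacts_per_stage = n_artifacts_per_stage,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate replicate transcript abundances for one AS event
#'
#' Inclusion/exclusion TPMs are drawn so that the recomputed PSI equals the
#' true PSI in expectation; per-replicate jitter is applied on the logit
#' scale with sd \code{psi_noise_sd}. True PSI of exactly 0 or 1 stays
#' exact under any noise.
#'
#' @param true_psi named numeric vector of per-stage true PSI in [0, 1]
#' @param config a \code{\link{simulation_config}}
#' @param total_tpm total abundance of the two forms (default
#'   \code{config$tpm_depth})
#' @return numeric matrix, rows c("inclusion", "exclusion"), one column per
#'   \code{<stage>_rep<k>}
#' @export
simulate_quantification <- function(true_psi, config, total_tpm = NULL) {
  stopifnot(all(true_psi >= 0 & true_psi <= 1))
  total_tpm <- total_tpm %||% config$tpm_depth
  if (total_tpm < 0) stop("tpm_depth must be positive")
  stages <- names(true_psi) %||% paste0("stage", seq_along(true_psi))
  cols <- as.vector(outer(stages, seq_len(config$n_replicates),
                          function(s, k) paste0(s, "_rep", k)))
  out <- matrix(0, nrow = 2, ncol = length(cols),
                dimnames = list(c("inclusion", "exclusion"), sort(cols)))
  for (si in seq_along(stages)) {
    for (k in seq_len(config$n_replicates)) {
      p <- plogis(qlogis(true_psi[si]) + rnorm(1, 0, config$psi_noise_sd))
      cn <- paste0(stages[si], "_rep", k)
      out["inclusion", cn] <- total_tpm * p
      out["exclusion", cn] <- total_tpm * (1 - p)
    }
  }
  out
}

# exon/intron t-coordinate layout from an architecture
arch_tcoords <- function(ex_len, in_len) {
  n <- length(ex_len)
  ex_start <- integer(n); ex_end <- integer(n)
  pos <- 1L
  for (j in seq_len(n)) {
    ex_start[j] <- pos
    ex_end[j] <- pos + ex_len[j] - 1L
    pos <- ex_end[j] + (if (j < n) in_len[j] else 0L) + 1L
  }
  list(start = ex_start, end = ex_end, L = ex_end[n])
}

# map t-intervals to genomic intervals for a gene at gstart, locus length L
map_genomic <- function(t1, t2, gstart, L, strand) {
  if (strand == "+") cbind(start = gstart + t1 - 1L, end = gstart + t2 - 1L)
  else cbind(start = gstart + L - t2, end = gstart + L - t1)
}

# alternative-isoform exon chain (t-coords) for a planted event
alt_chain_t <- function(tc, type, k, shift) {
  s <- tc$start; e <- tc$end
  switch(type,
    IR = { # merge exons k and k+1
      list(start = c(s[seq_len(k - 1)], s[k], s[-seq_len(k + 1)]),
           end = c(e[seq_len(k - 1)], e[k + 1], e[-seq_len(k + 1)]))
    },
    ES = { # drop exon k
      list(start = s[-k], end = e[-k])
    },
    A5SS = { # shorten exon k at its 3' (transcription) end
      e2 <- e; e2[k] <- e2[k] - shift
      list(start = s, end = e2)
    },
    A3SS = { # shorten exon k+1 at its 5' (transcription) end
      s2 <- s; s2[k + 1] <- s2[k + 1] + shift
      list(start = s2, end = e)
    })
}

# genomic event coordinates from the two genomic exon chains
event_coords_genomic <- function(type, ref_chain, alt_chain, strand) {
  introns_of <- function(ch) {
    o <- order(ch[, "start"])
    st <- ch[o, "start"]; en <- ch[o, "end"]
    if (length(st) < 2) return(cbind(s = integer(0), e = integer(0)))
    cbind(s = en[-length(en)] + 1L, e = st[-1] - 1L)
  }
  ri <- introns_of(ref_chain); ai <- introns_of(alt_chain)
  key <- function(m) paste(m[, 1], m[, 2])
  if (type == "IR") {
    d <- ri[!key(ri) %in% key(ai), , drop = FALSE]
    s <- d[1, 1]; e <- d[1, 2]
    o <- ref_chain[order(ref_chain[, "start"]), , drop = FALSE]
    a <- o[o[, "end"] == s - 1L, "start"]
    b <- o[o[, "start"] == e + 1L, "end"]
    c(a, s - 1L, e + 1L, b)
  } else if (type == "ES") {
    skip <- ai[!key(ai) %in% key(ri), , drop = FALSE]
    s1 <- skip[1, 1]; e2 <- skip[1, 2]
    inner <- ri[ri[, 1] >= s1 & ri[, 2] <= e2, , drop = FALSE]
    c(s1, inner[1, 2], inner[2, 1], e2)
  } else {
    r <- ri[!key(ri) %in% key(ai), , drop = FALSE]
    a <- ai[!key(ai) %in% key(ri), , drop = FALSE]
    if (r[1, 2] == a[1, 2]) { # shared end, differing start
      ss <- sort(c(r[1, 1], a[1, 1]))
      c(ss[1], r[1, 2], ss[2], r[1, 2])
    } else { # shared start, differing end
      ee <- sort(c(r[1, 2], a[1, 2]))
      c(r[1, 1], ee[1], r[1, 1], ee[2])
    }
  }
}
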