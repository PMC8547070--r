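#' Percent spliced in (PSI) per event and sample
#'
#' PSI = sum of inclusion-form transcript TPM / (inclusion + exclusion TPM),
#' NA when the denominator is zero. Member transcripts missing from the TPM
#' table count as zero abundance (with a warning).
#'
#' @param events event table from \code{\link{detect_events}}
#' @param expr TPM matrix (transcripts x samples)
#' @return numeric matrix events x samples, rownames = event_id
#' @export
compute_psi <- function(events, expr) {
  samples <- colnames(expr)
  psi <- matrix(NA_real_, nrow = nrow(events), ncol = length(samples),
                dimnames = list(events$event_id, samples))
  if (nrow(events) == 0) return(psi)
  members <- unique(unlist(c(events$inclusion, events$exclusion)))
  missing <- setdiff(members, rownames(expr))
  if (length(missing))
    warning(length(missing), " member transcript(s) missing from TPM table, ",
            "counted as 0 TPM")
  get_tpm <- function(tx) {
    tx <- intersect(tx, rownames(expr))
    if (!length(tx)) return(numeric(length(samples)))
    colSums(expr[tx, , drop = FALSE])
  }
  for (i in seq_len(nrow(events))) {
    inc <- get_tpm(events$inclusion[[i]])
    exc <- get_tpm(events$exclusion[[i]])
    tot <- inc + exc
    p <- ifelse(tot > 0, inc / tot, NA_real_)
    psi[i, ] <- p
  }
  psi
}

#' Per-stage mean PSI
#'
#' Arithmetic mean of the non-NA replicate PSI values; NA when every
#' replicate is NA.
#'
#' @param psi events x samples PSI matrix
#' @param stage_of named character vector sample -> stage
#' @return matrix events x stages
#' @export
stage_mean_psi <- function(psi, stage_of) {
  stopifnot(all(colnames(psi) %in% names(stage_of)))
  stages <- unique(stage_of[colnames(psi)])
  out <- sapply(stages, function(st) {
    cols <- colnames(psi)[stage_of[colnames(psi)] == st]
    rowMeans(psi[, cols, drop = FALSE], na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  out <- matrix(out, nrow = nrow(psi),
                dimnames = list(rownames(psi), stages))
  out
}

#' Call AS occurrence by the PSI window rule
#'
#' An event occurs at a stage (or in a sample) when its PSI lies in
#' \code{[0.05, 0.95]}, bounds inclusive. NA PSI yields NA (no call).
#'
#' @param psi matrix of PSI values (stage means or per-sample)
#' @param window inclusive PSI window
#' @param tol numeric slack on the window bounds
#' @return logical matrix of the same shape (NA where PSI is NA)
#' @export
call_occurrence <- function(psi, window = c(0.05, 0.95), tol = 1e-9) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  psi >= window[1] - tol & psi <= window[2] + tol
}

#' Partition events into stage-specificity classes
#'
#' @param occurrence logical matrix with columns for the two stages
#'   (NA = no call, treated as not occurring)
#' @param stages the two stage column names, first = early stage
#' @return factor per event with levels immature_only, ripe_only, both,
#'   neither
#' @export
call_stage_specific <- function(occurrence,
                                stages = c("immature", "ripe")) {
  stopifnot(all(stages %in% colnames(occurrence)))
  a <- occurrence[, stages[1]] %in% TRUE
  b <- occurrence[, stages[2]] %in% TRUE
  lab <- ifelse(a & b, "both",
         ifelse(a & !b, paste0(stages[1], "_only"),
         ifelse(!a & b, paste0(stages[2], "_only"), "neither")))
  factor(setNames(lab, rownames(occurrence)),
         levels = c(paste0(stages[1], "_only"), paste0(stages[2], "_only"),
                    "both", "neither"))
}

#' Differential splicing between stages
#'
#' Delta-PSI is the mean ripe PSI minus the mean immature PSI. The p-value
#' is empirical: between-replicate |PSI| differences, pooled across events
#' within total-abundance bins, form the null; the p-value is the smoothed
#' rank of the observed |dPSI| in its bin
#' \code{(1 + n null >= obs) / (1 + n null)}. An event is significant when
#' p < alpha and |dPSI| > dpsi_min. Events with NA PSI in any required
#' sample are excluded from testing and flagged.
#'
#' @param psi events x samples PSI matrix
#' @param events event table (for gene ids)
#' @param expr TPM matrix (for abundance binning)
#' @param stage_of named vector sample -> stage
#' @param stages the two stages, contrast = stages[2] - stages[1]
#' @param n_bins abundance bins for the empirical null
#' @param alpha,dpsi_min decision gates
#' @param fdr apply Benjamini-Hochberg correction before gating (off by
#'   default; the decision gates operate on raw p-values)
#' @return data.frame event_id, gene_id, dpsi, pvalue, tested, significant
#' @export
differential_splicing <- function(psi, events, expr, stage_of,
                                  stages = c("immature", "ripe"),
                                  n_bins = 3, alpha = 0.05, dpsi_min = 0.1,
                                  fdr = FALSE) {
  cols_a <- colnames(psi)[stage_of[colnames(psi)] == stages[1]]
  cols_b <- colnames(psi)[stage_of[colnames(psi)] == stages[2]]
  stopifnot(length(cols_a) >= 2, length(cols_b) >= 2)
  tested <- rowSums(is.na(psi[, c(cols_a, cols_b), drop = FALSE])) == 0
  dpsi <- rowMeans(psi[, cols_b, drop = FALSE]) -
    rowMeans(psi[, cols_a, drop = FALSE])

  # abundance per event: mean total member TPM across samples
  abundance <- vapply(seq_len(nrow(events)), function(i) {
    tx <- intersect(unique(c(events$inclusion[[i]], events$exclusion[[i]])),
                    rownames(expr))
    if (!length(tx)) return(0)
    mean(colSums(expr[tx, , drop = FALSE]))
  }, 1)
  names(abundance) <- events$event_id
  abundance <- abundance[rownames(psi)]

  idx <- which(tested)
  pval <- rep(NA_real_, nrow(psi))
  if (length(idx)) {
    n_bins_eff <- max(1L, min(n_bins, floor(length(idx) / 10)))
    br <- unique(stats::quantile(abundance[idx],
                                 probs = seq(0, 1, length.out = n_bins_eff + 1)))
    bin <- cut(abundance[idx], breaks = br, include.lowest = TRUE,
               labels = FALSE)
    # null: within-stage between-replicate |PSI| differences
    null_vals <- cbind(
      abs(psi[idx, cols_a[1]] - psi[idx, cols_a[2]]),
      abs(psi[idx, cols_b[1]] - psi[idx, cols_b[2]]))
    for (b in unique(bin)) {
      in_bin <- which(bin == b)
      pool <- as.numeric(null_vals[in_bin, , drop = FALSE])
      pool <- pool[!is.na(pool)]
      for (k in in_bin) {
        pval[idx[k]] <- (1 + sum(pool >= abs(dpsi[idx[k]]))) / (1 + length(pool))
      }
    }
  }
  p_gate <- if (fdr) stats::p.adjust(pval, method = "BH") else pval
  data.frame(
    event_id = rownames(psi),
    gene_id = events$gene_id[match(rownames(psi), events$event_id)],
    dpsi = dpsi, pvalue = pval, tested = tested,
    significant = tested & !is.na(p_gate) & p_gate < alpha &
      abs(dpsi) > dpsi_min,
    row.names = NULL)
}
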