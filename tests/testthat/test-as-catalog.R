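test_that("a cassette exon yields exactly one ES event", {
  txs <- tx_set(
    incl = list(gene = "g", exons = list(c(100, 200), c(400, 500),
                                         c(800, 900))),
    skip = list(gene = "g", exons = list(c(100, 200), c(800, 900))))
  ev <- detect_events(txs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "ES")
  expect_equal(ev$inclusion[[1]], "incl")
  expect_equal(ev$exclusion[[1]], "skip")
  expect_equal(c(ev$c1, ev$c2, ev$c3, ev$c4), c(201, 399, 501, 799))
})

test_that("retention of the third intron of a four-intron gene is one IR", {
  # SR-like gene: five exons, isoform retaining intron 3
  ex <- list(c(1, 100), c(201, 300), c(401, 500), c(601, 700), c(801, 900))
  ret <- list(c(1, 100), c(201, 300), c(401, 700), c(801, 900))
  txs <- tx_set(spliced = list(gene = "sr", exons = ex),
                retained = list(gene = "sr", exons = ret))
  ev <- detect_events(txs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "IR")
  expect_equal(c(ev$c1, ev$c2, ev$c3, ev$c4), c(401, 500, 601, 700))
  expect_equal(ev$inclusion[[1]], "retained")
})

test_that("strand flips the A5SS/A3SS labels", {
  plus <- tx_set(
    long = list(gene = "gp", exons = list(c(100, 260), c(400, 500))),
    short = list(gene = "gp", exons = list(c(100, 200), c(400, 500))))
  evp <- detect_events(plus)
  expect_equal(evp$type, "A5SS") # variable donor on +
  expect_equal(evp$inclusion[[1]], "long")
  minus <- tx_set(
    long = list(gene = "gm", strand = "-",
                exons = list(c(100, 260), c(400, 500))),
    short = list(gene = "gm", strand = "-",
                 exons = list(c(100, 200), c(400, 500))))
  evm <- detect_events(minus)
  expect_equal(evm$type, "A3SS") # same geometry is the acceptor side on -
})

test_that("event detection equals the brute-force pairwise oracle", {
  set.seed(42)
  for (rep in 1:50) {
    g <- random_gene(paste0("g", rep))
    ev <- detect_events(g)
    expect_identical(event_signatures(ev), oracle_event_set(g),
                     info = paste("gene", rep))
  }
})

test_that("PSI follows the inclusion/exclusion TPM ratio with NA semantics", {
  txs <- tx_set(
    incl = list(gene = "g", exons = list(c(100, 200), c(400, 500),
                                         c(800, 900))),
    skip = list(gene = "g", exons = list(c(100, 200), c(800, 900))))
  ev <- detect_events(txs)
  expr <- matrix(c(5, 5, 3, 0, 0, 0), nrow = 2,
                 dimnames = list(c("incl", "skip"), c("s1", "s2", "s3")))
  psi <- compute_psi(ev, expr)
  expect_equal(unname(psi[1, ]), c(0.5, 1.0, NA))
})

test_that("swapping inclusion and exclusion maps PSI to 1 - PSI", {
  b <- small_bundle(seed = 9)
  bt <- build_species(b, "cucumber")
  ev <- detect_events(bt$transcriptome)
  expr <- b$species_data$cucumber$tpm
  psi <- compute_psi(ev, expr)
  swapped <- ev
  tmp <- swapped$inclusion; swapped$inclusion <- swapped$exclusion
  swapped$exclusion <- tmp
  psi2 <- compute_psi(swapped, expr)
  expect_equal(psi2, 1 - psi, tolerance = 1e-12)
})

test_that("occurrence window is inclusive and NA-aware", {
  m <- matrix(c(0.05, 0.95, NA, 0.96, 0.049, 0.5), ncol = 2,
              dimnames = list(c("e1", "e2", "e3"),
                              c("immature", "ripe")))
  occ <- call_occurrence(m)
  expect_equal(unname(occ[, 1]), c(TRUE, TRUE, NA))
  expect_equal(unname(occ[, 2]), c(FALSE, FALSE, TRUE))
  # widening the window to [0, 1] makes every non-NA PSI occur
  occ_all <- call_occurrence(m, window = c(0, 1))
  expect_true(all(occ_all[!is.na(m)]))
})

test_that("stage means average non-NA replicates only", {
  psi <- matrix(c(0.02, NA, 0.4, 0.6), nrow = 1,
                dimnames = list("e", c("s_immature_rep1", "s_immature_rep2",
                                       "s_ripe_rep1", "s_ripe_rep2")))
  stage_of <- setNames(c("immature", "immature", "ripe", "ripe"),
                       colnames(psi))
  sm <- stage_mean_psi(psi, stage_of)
  expect_equal(unname(sm[1, "immature"]), 0.02)
  expect_equal(unname(sm[1, "ripe"]), 0.5)
  occ <- call_occurrence(sm)
  expect_false(occ[1, "immature"]) # 0.02 below the window
})

test_that("stage-specific partition matches the occurrence pattern", {
  occ <- matrix(c(TRUE, TRUE, FALSE, NA, FALSE, TRUE, TRUE, FALSE),
                ncol = 2, dimnames = list(paste0("e", 1:4),
                                          c("immature", "ripe")))
  lab <- call_stage_specific(occ)
  expect_equal(as.character(lab),
               c("immature_only", "both", "ripe_only", "neither"))
})

test_that("stage-specific calls recover the manifest labels exactly", {
  b <- small_bundle(seed = 10, psi_noise_sd = 0, n_orthogroups = 20,
                    frac_stage_specific = 0.5,
                    frac_artifact_transcripts = 0)
  for (sp in c("melon", "papaya")) {
    bt <- build_species(b, sp)
    ev <- detect_events(bt$transcriptome)
    d <- b$species_data[[sp]]
    psi <- compute_psi(ev, d$tpm)
    lab <- call_stage_specific(call_occurrence(stage_mean_psi(psi,
                                                              d$stage_of)))
    truth <- b$truth$events[b$truth$events$species == sp, ]
    expect_setequal(names(lab), truth$event_id)
    expect_equal(as.character(lab[truth$event_id]), truth$stage_label)
  }
})

test_that("differential splicing applies both decision gates", {
  # 100 null events + planted shifts, built directly on toy genes
  set.seed(21)
  n <- 100
  mk_gene <- function(i, base) {
    off <- (i - 1) * 2000
    tx_set_args <- list(
      list(gene = paste0("dg", i),
           exons = list(c(off + 100, off + 200), c(off + 400, off + 500),
                        c(off + 800, off + 900))),
      list(gene = paste0("dg", i),
           exons = list(c(off + 100, off + 200), c(off + 800, off + 900))))
    names(tx_set_args) <- paste0("dg", i, c(".i", ".s"))
    do.call(tx_set, tx_set_args)
  }
  txs <- do.call(rbind, lapply(seq_len(n + 2), mk_gene))
  ev <- detect_events(validate_asm(txs))
  samples <- c("x_immature_rep1", "x_immature_rep2", "x_ripe_rep1",
               "x_ripe_rep2")
  stage_of <- setNames(c("immature", "immature", "ripe", "ripe"), samples)
  expr <- matrix(0, nrow = 2 * (n + 2), ncol = 4,
                 dimnames = list(unique(txs$transcript_id), samples))
  jitter_psi <- function(p) plogis(qlogis(p) + rnorm(1, 0, 0.02))
  for (i in seq_len(n + 2)) {
    base_psi <- if (i == 1) c(0.25, 0.25, 0.75, 0.75)     # dPSI 0.5
    else if (i == 2) c(0.45, 0.45, 0.53, 0.53)            # dPSI 0.08
    else rep(runif(1, 0.2, 0.8), 4)                       # null
    for (k in 1:4) {
      # gene 3 carries exactly constant PSI (the zero-dPSI case)
      p <- if (i == 3) base_psi[k] else jitter_psi(base_psi[k])
      expr[paste0("dg", i, ".i"), k] <- 100 * p
      expr[paste0("dg", i, ".s"), k] <- 100 * (1 - p)
    }
  }
  psi <- compute_psi(ev, expr)
  res <- differential_splicing(psi, ev, expr, stage_of)
  res1 <- res[res$gene_id == "dg1", ]
  res2 <- res[res$gene_id == "dg2", ]
  expect_true(res1$significant)
  expect_lt(abs(res2$dpsi), 0.1)
  expect_false(res2$significant) # fails |dPSI| > 0.1 regardless of p
  # identical PSI across samples: dPSI 0, never significant
  res3 <- res[res$gene_id == "dg3", ]
  expect_equal(res3$dpsi, 0)
  expect_false(res3$significant)
})

test_that("gene-level summary counts AS genes among multiexon genes", {
  b <- small_bundle(seed = 12, frac_artifact_transcripts = 0,
                    n_orthogroups = 20)
  bt <- build_species(b, "cucumber")
  ev <- detect_events(bt$transcriptome)
  gs <- gene_level_summary(ev, bt$transcriptome)
  truth <- b$truth$events[b$truth$events$species == "cucumber", ]
  expect_equal(unname(gs$type_counts[c("IR", "ES", "A3SS", "A5SS")]),
               unname(table(factor(truth$type,
                                   levels = c("IR", "ES", "A3SS",
                                              "A5SS")))))
  expect_equal(gs$n_as_genes, length(unique(truth$gene_id)))
  # manifest-driven percentage
  multi <- gs$n_multiexon_genes
  expect_equal(gs$pct_as_genes, 100 * gs$n_as_genes / multi)
  # no events -> 0%
  gs0 <- gene_level_summary(ev[0, ], bt$transcriptome)
  expect_equal(gs0$pct_as_genes, 0)
})

test_that("retained introns are shorter than background in the fixture", {
  b <- small_bundle(seed = 13, n_orthogroups = 30,
                    frac_artifact_transcripts = 0)
  bt <- build_species(b, "cucumber")
  ev <- detect_events(bt$transcriptome)
  cmp <- intron_length_comparison(ev, bt$transcriptome,
                                  alternative = "less")
  expect_true(all(cmp$retained <= 150))
  expect_lt(cmp$test$p_value, 0.01)
  expect_error(intron_length_comparison(ev[ev$type != "IR", ],
                                        bt$transcriptome), "IR")
})
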