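# a deterministic toy genome + two-isoform gene for flank tests
toy_genome <- function(len = 6000, seed = 99) {
  set.seed(seed)
  Biostrings::DNAStringSet(setNames(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "chr1"))
}

test_that("flanks are capped at 300 bp and walk across introns", {
  txs <- tx_set(
    spliced = list(gene = "g", exons = list(c(1001, 1400), c(2001, 2400))),
    retained = list(gene = "g", exons = list(c(1001, 2400))))
  ev <- detect_events(txs)
  g <- toy_genome()
  fl <- extract_flanks(ev, txs, g, species = "sp")
  expect_equal(nrow(fl), 1)
  expect_equal(fl$len_up, 300)
  expect_equal(fl$len_down, 300)
  # flanks equal the exonic sequence adjacent to the junction
  expect_equal(fl$seq_up,
               as.character(Biostrings::subseq(g[["chr1"]], 1101, 1400)))
  expect_equal(fl$seq_down,
               as.character(Biostrings::subseq(g[["chr1"]], 2001, 2300)))
  # a junction walks across upstream introns when the exon is short
  txs2 <- tx_set(
    spliced = list(gene = "h", exons = list(c(101, 200), c(301, 360),
                                            c(1001, 1400))),
    retained = list(gene = "h", exons = list(c(101, 200), c(301, 1400))))
  ev2 <- detect_events(txs2)
  fl2 <- extract_flanks(ev2, txs2, g, species = "sp")
  expect_equal(fl2$len_up, 160) # 60 bp exon 2 + 100 bp exon 1
})

test_that("events with short flanks are excluded and reported", {
  txs <- tx_set(
    spliced = list(gene = "g", exons = list(c(101, 125), c(301, 340))),
    retained = list(gene = "g", exons = list(c(101, 340))))
  ev <- detect_events(txs)
  fl <- extract_flanks(ev, txs, toy_genome(), species = "sp")
  expect_equal(nrow(fl), 0)
  expect_equal(nrow(attr(fl, "excluded")), 1)
})

test_that("minus-strand flanks are the reverse complement at mirrored sides", {
  g <- toy_genome(seed = 77)
  plus <- tx_set(
    spliced = list(gene = "g", exons = list(c(1001, 1400), c(2001, 2400))),
    retained = list(gene = "g", exons = list(c(1001, 2400))))
  minus <- tx_set(
    spliced = list(gene = "g", strand = "-",
                   exons = list(c(1001, 1400), c(2001, 2400))),
    retained = list(gene = "g", strand = "-",
                    exons = list(c(1001, 2400))))
  flp <- extract_flanks(detect_events(plus), plus, g, species = "sp")
  flm <- extract_flanks(detect_events(minus), minus, g, species = "sp")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(flm$seq_up, rc(flp$seq_down))
  expect_equal(flm$seq_down, rc(flp$seq_up))
})

test_that("flank similarity groups by type and scores local identity", {
  set.seed(5)
  s1 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  flanks <- data.frame(
    species = c("a", "b", "a", "b"),
    event_id = c("e1", "e2", "e3", "e4"),
    type = c("IR", "IR", "ES", "ES"),
    gene_id = c("ga", "gb", "ga2", "gb2"),
    chrom = "chr1", strand = "+", jstart = 1L, jend = 2L,
    seq_up = s1, seq_down = s2,
    len_up = 150L, len_down = 150L)
  m <- pairwise_flank_similarity(flanks)
  # identical flanks match within a type; IR never compared against ES
  expect_equal(nrow(m), 2)
  expect_setequal(m$type, c("IR", "ES"))
  expect_equal(m$id_up, c(1, 1))
  # flanks independently diverged from an ancestor at rate 0.4 per branch
  # fail the default thresholds
  mut <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < rate
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(v, collapse = "")
  }
  flanks2 <- flanks[1:2, ]
  flanks2$seq_up <- c(mut(s1, 0.4), mut(s1, 0.4))
  flanks2$seq_down <- c(mut(s2, 0.4), mut(s2, 0.4))
  expect_equal(nrow(pairwise_flank_similarity(flanks2)), 0)
  # same-species records never match
  flanks3 <- flanks[1:2, ]; flanks3$species <- "a"
  expect_equal(nrow(pairwise_flank_similarity(flanks3)), 0)
})

test_that("conservation requires co-orthogroup membership", {
  matches <- data.frame(
    type = "IR", species_a = "a", event_a = "e1", gene_a = "ga",
    species_b = "b", event_b = "e2", gene_b = "gb",
    junction_a = "1-2", junction_b = "3-4", id_up = 1, id_down = 1)
  ogs_same <- list(OG1 = list(a = "ga", b = "gb"))
  ogs_diff <- list(OG1 = list(a = "ga"), OG2 = list(b = "gb"))
  cc1 <- detect_conserved(matches, ogs_same, c("a", "b"))
  expect_equal(nrow(cc1$clusters), 2) # one 2-species cluster
  expect_equal(length(unique(cc1$clusters$cluster_id)), 1)
  cc2 <- detect_conserved(matches, ogs_diff, c("a", "b"))
  expect_equal(nrow(cc2$clusters), 0)
})

test_that("planted conserved clusters are recovered on the bundle", {
  b <- small_bundle(seed = 15, n_orthogroups = 16,
                    frac_conserved_events = 0.25,
                    frac_artifact_transcripts = 0)
  species <- b$config$species
  builds <- lapply(setNames(species, species), function(s)
    build_species(b, s))
  evs <- lapply(builds, function(x) detect_events(x$transcriptome))
  flanks <- do.call(rbind, lapply(species, function(s)
    extract_flanks(evs[[s]], builds[[s]]$transcriptome,
                   b$species_data[[s]]$genome, species = s)))
  m <- pairwise_flank_similarity(flanks)
  cc <- detect_conserved(m, b$orthogroups, species)
  truth <- b$truth$clusters
  expect_equal(length(unique(cc$clusters$cluster_id)),
               length(unique(truth$cluster)))
  expect_setequal(cc$clusters$event_id, truth$event_id)
  # no cluster mixes types or spans two orthogroups
  for (ci in unique(cc$clusters$cluster_id)) {
    cl <- cc$clusters[cc$clusters$cluster_id == ci, ]
    expect_equal(length(unique(cl$type)), 1)
    ogs <- vapply(cl$gene_id, function(g)
      names(Filter(function(m2) g %in% unlist(m2), b$orthogroups))[1], "")
    expect_equal(length(unique(ogs)), 1)
  }
  # all planted clusters span all species -> all highly conserved
  hc <- call_highly_conserved(cc$clusters, species)
  expect_setequal(unique(hc$cluster_id), unique(cc$clusters$cluster_id))
  expect_equal(nrow(call_highly_conserved(cc$clusters,
                                          c(species, "extra_sp"))), 0)
  # counts matrix row sums equal per-species conserved event counts
  rs <- rowSums(cc$counts)
  for (sp in species)
    expect_equal(unname(rs[sp]),
                 sum(cc$clusters$species == sp))
  expect_equal(sum(cc$summary$species_pct), 100, tolerance = 0.05)
})

test_that("counts-matrix summary reproduces percentages from raw counts", {
  counts <- matrix(c(2, 0, 1, 0, 1, 1, 0, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("a", "b"),
                                   c("IR", "A3SS", "A5SS", "ES")))
  s <- summarize_conserved_counts(counts)
  expect_equal(s$grand_total, 5)
  expect_equal(unname(s$species_pct), c(60, 40))
  expect_equal(unname(s$type_pct), c(60, 20, 20, 0))
  expect_equal(s$table$total[s$table$species == "All"], 5)
})

test_that("conserved/nonconserved PSI contrast separates planted shifts", {
  # conserved events: equal stage PSI; nonconserved: +0.3 at ripe
  set.seed(31)
  n <- 60
  mk <- function(shift) {
    base <- runif(n, 0.2, 0.55)
    m <- cbind(immature = base, ripe = base + shift)
    rownames(m) <- paste0("e", seq_len(n), "_", shift)
    m
  }
  stage_psi <- list(spA = rbind(mk(0), mk(0.3)))
  conserved <- list(spA = rownames(stage_psi$spA)[1:n])
  out <- conserved_psi_contrast(stage_psi, conserved)
  expect_gt(out$conserved$test$p_value, 0.05)
  expect_lt(out$nonconserved$test$p_value, 0.01)
  # an empty conserved set omits that contrast with a warning
  expect_warning(
    conserved_psi_contrast(list(spA = mk(0.1)), list(spA = character(0))),
    "omitted")
  expect_null(suppressWarnings(
    conserved_psi_contrast(list(spA = mk(0.1)),
                           list(spA = character(0)))$conserved))
})
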