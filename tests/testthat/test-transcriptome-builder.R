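# three-gene toy annotation used by the class-code cases
toy_reference <- function() {
  tx_set(
    ref1 = list(gene = "gA", exons = list(c(100, 200), c(400, 500),
                                          c(800, 900))),
    ref2 = list(gene = "gB", strand = "-", exons = list(c(2000, 2100),
                                                        c(2500, 2600))),
    ref3 = list(gene = "gC", exons = list(c(5000, 5400))))
}

test_that("class codes follow the =, x, s, o, u definitions", {
  ref <- toy_reference()
  asm <- tx_set(
    same = list(gene = "x1", exons = list(c(100, 200), c(400, 500),
                                          c(800, 900))),
    inter = list(gene = "x2", exons = list(c(9000, 9100), c(9300, 9400))),
    anti = list(gene = "x3", strand = "-", exons = list(c(150, 250))),
    # single exon inside gA's first intron, opposite strand
    sint = list(gene = "x4", strand = "-", exons = list(c(240, 380))),
    over = list(gene = "x5", exons = list(c(120, 210), c(400, 520))))
  codes <- classify_vs_reference(asm, ref)
  expect_equal(unname(codes[c("same", "inter", "anti", "sint", "over")]),
               c("=", "u", "x", "s", "o"))
})

test_that("identity requires the full intron chain, not only overlap", {
  ref <- toy_reference()
  asm <- tx_set(longer = list(gene = "y", exons = list(c(80, 200),
                                                       c(400, 500),
                                                       c(800, 950))))
  # same introns, different terminal exon lengths: still "=" (chain match)
  expect_equal(unname(classify_vs_reference(asm, ref)["longer"]), "=")
  asm2 <- tx_set(skip = list(gene = "y", exons = list(c(100, 200),
                                                      c(800, 900))))
  expect_equal(unname(classify_vs_reference(asm2, ref)["skip"]), "o")
})

test_that("novel junctions are strand-sensitive set differences", {
  ref <- toy_reference()
  expect_equal(nrow(novel_junctions(ref, ref)), 0)
  # one exon-skipping isoform adds exactly the skip junction 201-799
  asm <- rbind(ref, tx_set(skip = list(gene = "gA",
                                       exons = list(c(100, 200),
                                                    c(800, 900)))))
  nj <- novel_junctions(validate_asm(asm), ref)
  expect_equal(nrow(nj), 1)
  expect_equal(c(nj$start, nj$end), c(201, 799))
  # strand-flipped copy of a reference intron is novel
  flip <- tx_set(f = list(gene = "gF", strand = "-",
                          exons = list(c(100, 200), c(400, 500))))
  njf <- novel_junctions(flip, ref)
  expect_equal(nrow(njf), 1)
})

test_that("junction support keep rule matches its truth table", {
  # KEEP iff (both >= 4) OR (either >= 10), enumerated over counts 0..12
  grid <- expand.grid(c1 = 0:12, c2 = 0:12)
  literal <- with(grid, (c1 >= 4 & c2 >= 4) | (c1 >= 10 | c2 >= 10))
  ref <- toy_reference()
  for (i in seq_len(nrow(grid))) {
    asm <- tx_set(t1 = list(gene = "gA", exons = list(c(100, 200),
                                                      c(800, 900))))
    support <- data.frame(chrom = "chr1", start = 201, end = 799,
                          strand = "+", count_rep1 = grid$c1[i],
                          count_rep2 = grid$c2[i])
    res <- filter_by_junction_support(asm, novel_junctions(asm, ref),
                                      support)
    expect_equal(nrow(res$kept) > 0, literal[i],
                 info = paste(grid$c1[i], grid$c2[i]))
  }
})

test_that("boundary junction-support cases behave as specified", {
  ref <- toy_reference()
  asm <- tx_set(t1 = list(gene = "gA", exons = list(c(100, 200),
                                                    c(800, 900))))
  nov <- novel_junctions(asm, ref)
  keep_with <- function(c1, c2) {
    s <- data.frame(chrom = "chr1", start = 201, end = 799, strand = "+",
                    count_rep1 = c1, count_rep2 = c2)
    nrow(filter_by_junction_support(asm, nov, s)$kept) > 0
  }
  expect_true(keep_with(4, 4))
  expect_true(keep_with(12, 0))
  expect_true(keep_with(0, 10))
  expect_false(keep_with(3, 9))
  # junction absent from the table counts as zero
  s0 <- data.frame(chrom = "chr1", start = 1, end = 2, strand = "+",
                   count_rep1 = 50, count_rep2 = 50)
  expect_false(nrow(filter_by_junction_support(asm, nov, s0)$kept) > 0)
})

test_that("expression filter is strict in both replicates", {
  asm <- tx_set(
    t1 = list(gene = "g1", exons = list(c(1, 100))),
    t2 = list(gene = "g2", exons = list(c(200, 300))),
    t3 = list(gene = "g3", exons = list(c(400, 500))))
  expr <- matrix(c(1.0, 5.0, 1.01, 1.01, 8, 0.9), nrow = 3, byrow = TRUE,
                 dimnames = list(c("t1", "t2", "t3"), c("r1", "r2")))
  res <- filter_by_expression(asm, expr, c("r1", "r2"))
  expect_setequal(unique(res$kept$transcript_id), "t2")
  expect_setequal(res$removed$transcript_id, c("t1", "t3"))
  expect_true(all(res$removed$reason == "TPM"))
})

test_that("single-exon filter keeps only reference-identical monoexonics", {
  ref <- toy_reference()
  asm <- tx_set(
    exact = list(gene = "gC", exons = list(c(5000, 5400))),
    near = list(gene = "gC", exons = list(c(5000, 5300))),
    multi = list(gene = "gA", exons = list(c(100, 200), c(400, 500))))
  res <- filter_single_exon(asm, ref)
  expect_setequal(unique(res$kept$transcript_id), c("exact", "multi"))
  expect_equal(res$removed$transcript_id, "near")
})

test_that("stage merge keeps the longer transcript per intron chain", {
  a <- tx_set(im1 = list(gene = "g", exons = list(c(100, 200), c(400, 520))))
  b <- tx_set(rp1 = list(gene = "g", exons = list(c(100, 200), c(400, 500))))
  m <- merge_stages(list(a, b))
  expect_equal(unique(m$transcript_id), "im1") # 221 bp beats 201 bp
  # different intron chains both kept
  c2 <- tx_set(rp2 = list(gene = "g", exons = list(c(100, 210),
                                                   c(400, 500))))
  m2 <- merge_stages(list(a, c2))
  expect_setequal(unique(m2$transcript_id), c("im1", "rp2"))
  # identical transcripts collapse to one copy
  m3 <- merge_stages(list(a, a))
  expect_equal(length(unique(m3$transcript_id)), 1)
})

test_that("the cascade removes exactly the planted artefacts", {
  b <- small_bundle(seed = 3, frac_stage_specific = 0,
                    n_artifacts_per_stage = 4)
  for (sp in c("cucumber", "peach")) {
    bt <- build_species(b, sp)
    rem <- bt$removals
    expect_equal(nrow(rem), 8) # 4 flavours x 2 stages
    expect_equal(sort(unique(rem$reason)),
                 c("CLASS", "JUNC", "MONO", "TPM"))
    for (st in c("immature", "ripe"))
      expect_equal(sort(rem$reason[rem$stage == st]),
                   c("CLASS", "JUNC", "MONO", "TPM"))
    expect_setequal(unique(bt$transcriptome$transcript_id),
                    b$truth$final_transcripts[[sp]])
  }
})

test_that("filter order does not change the final set on the fixture", {
  b <- small_bundle(seed = 5, frac_stage_specific = 0,
                    n_artifacts_per_stage = 4)
  d <- b$species_data$melon
  # manual cascade with class codes applied before expression
  final_ids <- function(order_fun) {
    per_stage <- lapply(names(d$assembled), function(st) {
      cur <- d$assembled[[st]]
      codes <- classify_vs_reference(cur, d$reference)
      nov <- novel_junctions(cur, d$reference)
      order_fun(cur, codes, nov, st)
    })
    sort(unique(merge_stages(per_stage)$transcript_id))
  }
  default_order <- function(cur, codes, nov, st) {
    cur <- filter_by_junction_support(cur, nov, d$junctions[[st]])$kept
    cur <- filter_by_expression(cur, d$tpm, d$stage_columns[[st]])$kept
    cur <- filter_by_class_code(cur, codes)$kept
    filter_single_exon(cur, d$reference)$kept
  }
  swapped <- function(cur, codes, nov, st) {
    cur <- filter_by_class_code(cur, codes)$kept
    cur <- filter_single_exon(cur, d$reference)$kept
    cur <- filter_by_junction_support(cur, nov, d$junctions[[st]])$kept
    filter_by_expression(cur, d$tpm, d$stage_columns[[st]])$kept
  }
  expect_identical(final_ids(default_order), final_ids(swapped))
})

test_that("builder invariants: no invented introns, idempotence, monotone", {
  b <- small_bundle(seed = 6)
  d <- b$species_data$papaya
  bt <- build_species(b, "papaya")
  out_in <- transcript_introns(bt$transcriptome)
  in_in <- do.call(rbind, lapply(d$assembled, transcript_introns))
  expect_true(all(junction_keys(out_in) %in% junction_keys(in_in)))
  # idempotence: rerunning on its own output changes nothing
  again <- build_high_quality_transcriptome(
    list(immature = bt$transcriptome, ripe = bt$transcriptome),
    d$reference, d$junctions, d$tpm, d$stage_columns)
  expect_setequal(unique(again$transcriptome$transcript_id),
                  unique(bt$transcriptome$transcript_id))
  # raising the TPM threshold never increases survivors
  n_at <- vapply(c(1, 2, 5, 20), function(thr) {
    length(unique(build_high_quality_transcriptome(
      d$assembled, d$reference, d$junctions, d$tpm, d$stage_columns,
      tpm_min = thr)$transcriptome$transcript_id))
  }, 1L)
  expect_true(all(diff(n_at) <= 0))
})

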