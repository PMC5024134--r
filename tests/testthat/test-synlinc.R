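test_that("immediate flanks are the nearest fully-left/right genes", {
  coding <- make_ts(
    list(id = "gl", locus = "gl", exons = list(c(0, 100)), biotype = "coding"),
    list(id = "gr", locus = "gr", exons = list(c(900, 1000)),
         biotype = "coding"))
  spans <- locus_spans(coding)
  linc <- data.frame(chrom = "chr1", start = 400, end = 500)
  fl <- flanking_genes(linc, spans)
  expect_equal(fl$upstream, "gl")
  expect_equal(fl$downstream, "gr")
  first <- data.frame(chrom = "chr1", start = 0, end = 50)
  # an overlapping gene is not a flank
  fl2 <- flanking_genes(first, spans)
  expect_true(is.na(fl2$upstream))
  expect_equal(fl2$downstream, "gr")
  alone <- data.frame(chrom = "chr9", start = 10, end = 20)
  fl3 <- flanking_genes(alone, spans)
  expect_true(is.na(fl3$upstream) && is.na(fl3$downstream))
})

test_that("flank ties break deterministically by locus id", {
  coding <- make_ts(
    list(id = "zz", locus = "zz", exons = list(c(0, 100)), biotype = "coding"),
    list(id = "aa", locus = "aa", exons = list(c(50, 100)), biotype = "coding"))
  fl <- flanking_genes(data.frame(chrom = "chr1", start = 200, end = 300),
                       locus_spans(coding))
  expect_equal(fl$upstream, "aa")
  # vectorised flank table agrees with the row-wise function
  lincs <- make_ts(list(id = "L", exons = list(c(200, 300))))
  ft <- lncdev:::.flank_table(lincs, coding)
  expect_equal(ft$upstream, "aa")
})

test_that("pairwise synteny follows the shared-orthologous-flank rule", {
  c1 <- make_ts(
    list(id = "g1", locus = "g1", exons = list(c(0, 100)), biotype = "coding"),
    list(id = "g2", locus = "g2", exons = list(c(900, 1000)),
         biotype = "coding"))
  l1 <- make_ts(list(id = "lincA", exons = list(c(400, 500))))
  c2 <- make_ts(
    list(id = "h1", locus = "h1", exons = list(c(0, 100)), biotype = "coding"),
    list(id = "h9", locus = "h9", exons = list(c(900, 1000)),
         biotype = "coding"))
  l2 <- make_ts(list(id = "lincB", exons = list(c(400, 500))))
  orth <- data.frame(gene_a = "g1", gene_b = "h1")
  calls <- pairwise_synteny(l1, c1, l2, c2, orth)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$linc_a, "lincA")
  expect_equal(calls$linc_b, "lincB")
  expect_equal(calls$shared_flank, "upstream:upstream")
  expect_true(calls$orientation_conserved)
  # no orthologous flanks -> no call
  none <- pairwise_synteny(l1, c1, l2, c2,
                           data.frame(gene_a = "g1", gene_b = "h9"))
  expect_equal(nrow(none), 1)       # g1 upstream of lincA, h9 downstream of lincB
  expect_equal(none$shared_flank, "upstream:downstream")
  expect_false(none$orientation_conserved)
  empty <- pairwise_synteny(l1, c1, l2, c2,
                            data.frame(gene_a = "gX", gene_b = "h1"))
  expect_equal(nrow(empty), 0)
})

test_that("orientation conservation compares side and relative strand", {
  c1 <- make_ts(list(id = "g1", locus = "g1", exons = list(c(0, 100)),
                     strand = "+", biotype = "coding"))
  c2 <- make_ts(list(id = "h1", locus = "h1", exons = list(c(0, 100)),
                     strand = "-", biotype = "coding"))
  orth <- data.frame(gene_a = "g1", gene_b = "h1")
  lp <- make_ts(list(id = "la", exons = list(c(400, 500)), strand = "+"))
  lm <- make_ts(list(id = "lb", exons = list(c(400, 500)), strand = "-"))
  # la is + next to + gene (rel TRUE); lb is - next to - gene (rel TRUE)
  expect_true(pairwise_synteny(lp, c1, lm, c2, orth)$orientation_conserved)
  # lb' is + next to - gene (rel FALSE) -> not orientation conserved
  lb2 <- make_ts(list(id = "lb2", exons = list(c(400, 500)), strand = "+"))
  expect_false(pairwise_synteny(lp, c1, lb2, c2, orth)$orientation_conserved)
})

test_that("synteny calls equal the brute-force oracle and are symmetric", {
  ds <- simulate_dataset(small_config(seed = 31))
  spA <- names(ds$species_models)[1]
  spB <- names(ds$species_models)[2]
  mA <- ds$species_models[[spA]]
  mB <- ds$species_models[[spB]]
  truth_linc <- names(ds$truth$biotype)[ds$truth$biotype == "lincRNA"]
  lincsA <- subset_transcripts(mA, truth_linc)
  codingA <- subset_transcripts(mA, mA$transcripts$transcript_id[
    ds$truth$biotype[mA$transcripts$transcript_id] == "coding"])
  lincsB <- subset_transcripts(mB, mB$transcripts$transcript_id[
    mB$transcripts$biotype == "lincRNA"])
  codingB <- subset_transcripts(mB, mB$transcripts$transcript_id[
    mB$transcripts$biotype == "coding"])
  calls <- pairwise_synteny(lincsA, codingA, lincsB, codingB, ds$orthology)
  oracle <- brute_pairwise_synteny(lincsA, codingA, lincsB, codingB,
                                   ds$orthology)
  expect_equal(calls[, c("linc_a", "linc_b")], oracle,
               ignore_attr = TRUE)
  # planted pairs are all present
  sp <- ds$truth$syntenic_pairs
  expect_true(all(paste(sp$linc_a, sp$linc_b) %in%
                    paste(calls$linc_a, calls$linc_b)))
  # symmetry: swapping the species transposes the calls
  rev_orth <- data.frame(gene_a = ds$orthology$gene_b,
                         gene_b = ds$orthology$gene_a)
  back <- pairwise_synteny(lincsB, codingB, lincsA, codingA, rev_orth)
  expect_setequal(paste(calls$linc_a, calls$linc_b),
                  paste(back$linc_b, back$linc_a))
})

test_that("a distant unrelated gene changes no synteny call", {
  c1 <- make_ts(
    list(id = "g1", locus = "g1", exons = list(c(0, 100)), biotype = "coding"),
    list(id = "g2", locus = "g2", exons = list(c(900, 1000)),
         biotype = "coding"))
  l1 <- make_ts(list(id = "lincA", exons = list(c(400, 500))))
  orth <- data.frame(gene_a = "g1", gene_b = "g1")
  before <- pairwise_synteny(l1, c1, l1, c1, orth)
  far <- make_ts(list(id = "far", locus = "far", chrom = "chr7",
                      exons = list(c(0, 100)), biotype = "coding"))
  after <- pairwise_synteny(l1, bind_transcripts(c1, far), l1,
                            bind_transcripts(c1, far), orth)
  expect_equal(before, after)
})

test_that("multi-species intersection requires synteny with every species", {
  calls <- list(
    "A|B" = data.frame(linc_a = c("a1", "a2"), linc_b = c("b1", "b2")),
    "A|C" = data.frame(linc_a = "a1", linc_b = "c1"),
    "B|C" = data.frame(linc_a = "b1", linc_b = "c1"))
  ms <- multi_species_synteny(calls, c("A", "B", "C"))
  expect_equal(ms$A, "a1")       # a2 lacks a partner in C
  expect_equal(ms$B, "b1")
  expect_equal(ms$C, "c1")
  # invariant to species order
  ms2 <- multi_species_synteny(calls, c("C", "B", "A"))
  expect_equal(ms2$A, ms$A)
})

test_that("randomisation test reports Z on planted synteny and a safe fallback", {
  ds <- simulate_dataset(small_config(seed = 31))
  spA <- names(ds$species_models)[1]
  spB <- names(ds$species_models)[2]
  mA <- ds$species_models[[spA]]; mB <- ds$species_models[[spB]]
  truth_linc <- names(ds$truth$biotype)[ds$truth$biotype == "lincRNA"]
  lincs <- stats::setNames(list(
    subset_transcripts(mA, truth_linc),
    subset_transcripts(mB, mB$transcripts$transcript_id[
      mB$transcripts$biotype == "lincRNA"])), c(spA, spB))
  coding <- stats::setNames(list(
    subset_transcripts(mA, mA$transcripts$transcript_id[
      ds$truth$biotype[mA$transcripts$transcript_id] == "coding"]),
    subset_transcripts(mB, mB$transcripts$transcript_id[
      mB$transcripts$biotype == "coding"])), c(spA, spB))
  maps <- stats::setNames(list(ds$orthology), paste0(spA, "|", spB))
  genomes <- stats::setNames(list(ds$genome, ds$genome), c(spA, spB))
  rt <- synteny_randomization(lincs, coding, maps, genomes, n_reps = 20,
                              seed = 5)
  expect_gt(rt$z, 2)
  expect_lt(rt$p, 0.05)
  rt2 <- synteny_randomization(lincs, coding, maps, genomes, n_reps = 20,
                               seed = 5)
  expect_identical(rt[c("observed", "null", "z", "p")],
                   rt2[c("observed", "null", "z", "p")])
  # empty orthology: observed and null are all zero, sd = 0 -> empirical p
  none <- stats::setNames(list(ds$orthology[0, ]), paste0(spA, "|", spB))
  rt3 <- synteny_randomization(lincs, coding, none, genomes, n_reps = 5,
                               seed = 1)
  expect_true(is.na(rt3$z))
  expect_equal(rt3$p, 1)
})
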