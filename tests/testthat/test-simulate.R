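test_that("identical seeds give identical datasets", {
  d1 <- simulate_dataset(small_config(seed = 4))
  d2 <- simulate_dataset(small_config(seed = 4))
  expect_identical(d1$models, d2$models)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$blocks, d2$blocks)
  expect_identical(d1$repeats, d2$repeats)
  expect_identical(d1$cage, d2$cage)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(small_config(seed = 5))
  expect_false(identical(d1$counts$counts, d3$counts$counts))
})

test_that("every generated feature lies within its chromosome", {
  ds <- simulate_dataset(small_config(seed = 8))
  for (m in ds$species_models) {
    expect_true(all(m$exons$start >= 0))
    expect_true(all(m$exons$end <= ds$genome[m$exons$chrom]))
  }
  expect_true(all(ds$repeats$end <= ds$genome[ds$repeats$chrom]))
  expect_true(all(ds$blocks$end <= ds$genome[ds$blocks$chrom]))
})

test_that("lncRNAs have fewer but longer exons and lower expression", {
  ds <- simulate_dataset(small_config(seed = 8))
  tr <- ds$truth
  lnc <- names(tr$biotype)[tr$biotype %in% c("lncRNA", "lincRNA")]
  cod <- names(tr$biotype)[tr$biotype == "coding" & !(names(tr$biotype) %in% tr$decoys)]
  nex <- n_exons(ds$models)
  expect_lt(mean(nex[lnc]), mean(nex[cod]))
  ew <- ds$models$exons
  ew$w <- ew$end - ew$start
  expect_gt(mean(ew$w[ew$transcript_id %in% lnc]),
            mean(ew$w[ew$transcript_id %in% cod]))
  expect_lt(mean(rowMeans(ds$counts$counts[lnc, ])),
            mean(rowMeans(ds$counts$counts[cod, ])))
})

test_that("counts carry the planted stage structure", {
  ds <- simulate_dataset(small_config(seed = 8))
  tr <- ds$truth
  cm <- ds$counts
  expect_equal(unname(cm$library_sizes), unname(colSums(cm$counts)))
  mat <- names(tr$expression)[tr$expression == "maternal"]
  emb <- names(tr$expression)[tr$expression == "embryonic"]
  expect_gt(mean(cm$counts[mat, "egg"]), mean(cm$counts[mat, "hpf24"]))
  expect_lt(mean(cm$counts[emb, "egg"]), mean(cm$counts[emb, "hpf24"]))
})

test_that("the Poisson limit of the count model has var ~ mean", {
  cfg <- small_config(seed = 3, dispersion_true = 1e-6,
                      depth_range = c(1, 1))
  ds <- simulate_dataset(cfg)
  hk <- ds$truth$housekeeping_transcript_ids
  y <- ds$counts$counts[hk, ]
  ratio <- apply(y, 1, stats::var) / pmax(rowMeans(y), 1e-9)
  # each row gives a chi-square-like ratio with 2 df; the mean over many
  # housekeeping transcripts concentrates near 1
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("planted conserved lncRNAs have blocks over their exons in both species", {
  ds <- simulate_dataset(small_config(seed = 8))
  cp <- ds$truth$conserved_pairs
  for (k in seq_len(nrow(cp))) {
    for (sp in names(ds$species_models)) {
      tid <- if (sp == names(ds$species_models)[1]) cp$linc_a[k] else cp$linc_b[k]
      ex <- ds$species_models[[sp]]$exons
      ex <- ex[ex$transcript_id == tid, , drop = FALSE]
      b <- ds$blocks[ds$blocks$species == sp, , drop = FALSE]
      ovl <- vapply(seq_len(nrow(b)), function(i)
        any(overlap_length(b[i, c("chrom", "start", "end")],
                           ex[, c("chrom", "start", "end")]) > 0), NA)
      expect_true(any(ovl))
    }
  }
  # block elements have one element per species
  tab <- table(ds$blocks$block_id)
  expect_true(all(tab == 2))
})

test_that("orthology table is symmetric across the species pair", {
  ds <- simulate_dataset(small_config(seed = 8))
  o <- ds$orthology
  expect_equal(sub("^spA_", "", o$gene_a), sub("^spB_", "", o$gene_b))
})

test_that("CAGE support in the classified set matches the configured fraction", {
  ds <- simulate_dataset(small_config(seed = 8))
  cls <- classify_transcripts(ds$models, ds$annotation, cage = ds$cage)
  res <- cls$results
  lnc <- res$transcript_id[res$stage_reached %in% c("lncRNA", "lincRNA")]
  frac <- mean(res$cage_supported[res$transcript_id %in% lnc])
  expect_lt(abs(frac - 0.85), 0.18)
  # planted support flags agree with the detector
  sup <- ds$truth$cage_supported[lnc]
  det <- stats::setNames(res$cage_supported, res$transcript_id)[lnc]
  expect_true(all(det[sup]))
})

test_that("truth labels survive a serialisation round trip", {
  ds <- simulate_dataset(small_config(seed = 8))
  f <- tempfile(fileext = ".json")
  write_truth(ds$truth, f)
  back <- read_truth(f)
  expect_equal(back$biotype, ds$truth$biotype)
  expect_equal(back$expression, ds$truth$expression)
  expect_equal(back$housekeeping_transcript_ids,
               ds$truth$housekeeping_transcript_ids)
  expect_equal(back$syntenic_pairs$linc_a, ds$truth$syntenic_pairs$linc_a)
  expect_equal(sort(unlist(back$te_loci$lncRNA)),
               sort(ds$truth$te_loci$lncRNA))
})

test_that("a dataset without lncRNAs yields no hitless short-ORF records", {
  cfg <- small_config(seed = 2, n_lncRNA = 0, n_decoy = 0, n_short = 0,
                      frac_lnc_violation = 0, frac_lnc_genic = 0,
                      n_planted_syntenic = 0, n_planted_conserved = 0,
                      n_te_lnc_loci = 0, n_tss_ltr_lnc = 0)
  ann <- simulate_annotation(cfg)$annotation
  cand <- !ann$has_protein_hit & !ann$has_domain_hit & !ann$has_ncrna_hit &
    ann$longest_orf_aa < 100
  expect_equal(sum(cand), 0)
})

test_that("a genome that is too small raises an explicit error", {
  cfg <- small_config(seed = 1,
                      genome = stats::setNames(rep(40000, 2), c("c1", "c2")))
  expect_error(simulate_annotation(cfg), "genome too small")
})
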