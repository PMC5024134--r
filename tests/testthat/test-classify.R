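test_that("minimum-length filter is strict at 200 nt", {
  ts <- make_ts(list(id = "len200", exons = list(c(0, 200))),
                list(id = "len201", exons = list(c(1000, 1201))),
                list(id = "spliced", exons = list(c(2000, 2100), c(2500, 2601))))
  kept <- filter_min_length(ts)
  expect_setequal(kept$transcripts$transcript_id, c("len201", "spliced"))
  kept_ge <- filter_min_length(ts, strict = FALSE)
  expect_setequal(kept_ge$transcripts$transcript_id,
                  c("len200", "len201", "spliced"))
  empty <- filter_min_length(make_ts(list(id = "x", exons = list(c(0, 50)))))
  expect_equal(nrow(empty$transcripts), 0)
})

test_that("candidate call applies the homology and 100-aa ORF rules", {
  rec <- data.frame(
    transcript_id = c("a", "b", "c", "d", "e"),
    has_protein_hit = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    has_domain_hit = FALSE,
    has_ncrna_hit = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    longest_orf_aa = c(99, 100, 50, 10, 20),
    ncp = 0.5, has_swissprot_hit = FALSE)
  expect_setequal(call_candidates(rec), c("a", "d"))
  expect_error(call_candidates(rbind(rec, rec[1, ])), "duplicate")
})

test_that("NCP cutoff is the candidate mean, applied strictly", {
  rec <- data.frame(transcript_id = c("x", "y", "z"),
                    ncp = c(0.60, 0.80, 0.88))
  cut <- ncp_cutoff(rec)
  expect_equal(cut, 0.76)
  expect_setequal(rec$transcript_id[rec$ncp > cut], c("y", "z"))
  same <- data.frame(transcript_id = c("x", "y"), ncp = c(0.7, 0.7))
  expect_equal(sum(same$ncp > ncp_cutoff(same)), 0)
  single <- data.frame(transcript_id = "x", ncp = 0.9)
  expect_equal(sum(single$ncp > ncp_cutoff(single)), 0)
  expect_error(ncp_cutoff(rec[0, ]), "no candidate")
})

test_that("positional filter applies the 5-kb downstream strand rules", {
  coding <- make_ts(list(id = "gene", locus = "gene",
                         exons = list(c(0, 1000)), biotype = "coding"))
  # downstream window of the plus-strand gene: [1000, 6000)
  mk <- function(id, start, strand, mono = FALSE)
    list(id = id, strand = strand,
         exons = if (mono) list(c(start, start + 500))
           else list(c(start, start + 200), c(start + 400, start + 700)))
  pot <- make_ts(
    mk("multi_4999", 5999, "+"),        # starts 4999 bp past the 3' end
    mk("multi_5001", 7001, "+"),
    mk("multi_at_bound", 6000, "+"),    # exactly 5000 bp past: kept
    mk("anti_multi_down", 5999, "-"),   # antisense multi-exon downstream: kept
    mk("anti_multi_ovl", 500, "-"),     # antisense multi-exon overlap: kept
    mk("sense_ovl", 500, "+"),
    mk("mono_anti_ovl", 500, "-", mono = TRUE),
    mk("mono_anti_down", 5999, "-", mono = TRUE))
  pf <- positional_filter(pot, coding)
  expect_setequal(pf$removed$transcript_id,
                  c("multi_4999", "sense_ovl", "mono_anti_ovl",
                    "mono_anti_down"))
  expect_setequal(pf$kept$transcripts$transcript_id,
                  c("multi_5001", "multi_at_bound", "anti_multi_down",
                    "anti_multi_ovl"))
  reasons <- stats::setNames(pf$removed$reason, pf$removed$transcript_id)
  expect_equal(unname(reasons["multi_4999"]),
               "same_strand_downstream_of_coding")
  expect_equal(unname(reasons["mono_anti_ovl"]), "mono_exonic_overlaps_coding")
  expect_equal(unname(reasons["mono_anti_down"]),
               "mono_exonic_downstream_of_coding")
})

test_that("downstream is measured in the coding gene's orientation", {
  minus_gene <- make_ts(list(id = "g", locus = "g", strand = "-",
                             exons = list(c(10000, 11000)), biotype = "coding"))
  # 3' end of a minus-strand gene is its start; window [5000, 10000)
  down <- make_ts(list(id = "m", strand = "-",
                       exons = list(c(6000, 6300))))  # mono, in window
  up <- make_ts(list(id = "u", strand = "-",
                     exons = list(c(12000, 12300)))) # 5' side: kept
  expect_equal(positional_filter(down, minus_gene)$removed$reason,
               "mono_exonic_downstream_of_coding")
  expect_equal(nrow(positional_filter(up, minus_gene)$removed), 0)
})

test_that("lincRNA call is strand-agnostic against the full coding locus", {
  coding <- make_ts(list(id = "g", locus = "g",
                         exons = list(c(0, 100), c(5000, 6000)),
                         biotype = "coding"))
  lnc <- make_ts(
    list(id = "intronic_anti", strand = "-",
         exons = list(c(1000, 1200), c(2000, 2300))),
    list(id = "adjacent", exons = list(c(6001, 6500), c(6800, 7200))),
    list(id = "abutting", exons = list(c(6000, 6400), c(6700, 7100))))
  linc <- call_lincRNAs(lnc, coding)
  expect_setequal(linc, c("adjacent", "abutting"))
  expect_setequal(call_lincRNAs(lnc, make_ts(list(id = "far", chrom = "chr9",
                                                  exons = list(c(0, 10)),
                                                  biotype = "coding"))),
                  lnc$transcripts$transcript_id)
})

test_that("CAGE support uses the oriented -1000/+400 window at 0.5 tpm", {
  ts <- make_ts(list(id = "plus", exons = list(c(10000, 12000))),
                list(id = "minus", strand = "-",
                     exons = list(c(30000, 32000))))
  tag <- function(pos, tpm, strand = "+")
    data.frame(chrom = "chr1", pos = pos, strand = strand, tpm = tpm)
  expect_true(cage_support(ts, tag(10000 - 500, 0.6))[["plus"]])
  expect_false(cage_support(ts, tag(10000 - 500, 0.4))[["plus"]])
  expect_false(cage_support(ts, tag(10000 + 500, 0.6))[["plus"]])
  expect_true(cage_support(ts, tag(10000 + 400, 0.5))[["plus"]])
  expect_true(cage_support(ts, tag(10000 - 1000, 0.5))[["plus"]])
  expect_false(cage_support(ts, tag(10000 - 1001, 0.5))[["plus"]])
  # minus strand: TSS at 31999, upstream means larger coordinates
  expect_true(cage_support(ts, tag(31999 + 500, 0.6, "-"))[["minus"]])
  expect_false(cage_support(ts, tag(31999 - 500, 0.6, "-"))[["minus"]])
  expect_true(cage_support(ts, tag(31999 - 400, 0.6, "-"))[["minus"]])
  # invariant to duplication and order
  tags <- rbind(tag(10000 + 500, 0.6), tag(10000 - 500, 0.6))
  expect_equal(cage_support(ts, tags), cage_support(ts, tags[c(2, 1, 1), ]))
})

test_that("reference mapping labels common/EST/novel loci with extensions", {
  assembled <- make_ts(
    list(id = "a1", locus = "A", exons = list(c(90, 310))),
    list(id = "b1", locus = "B", exons = list(c(5000, 5400))),
    list(id = "c1", locus = "C", exons = list(c(9000, 9400))),
    list(id = "d1", locus = "D", strand = "-",
         exons = list(c(20000, 20500))))
  reference <- make_ts(
    list(id = "r1", locus = "R1", exons = list(c(100, 300))),
    list(id = "r2", locus = "R2", strand = "-",
         exons = list(c(20100, 20400))))
  ests <- genome_intervals("chr1", 5100, 5200)
  res <- map_to_reference(assembled, reference, ests)
  res <- res[match(c("A", "B", "C", "D"), res$locus_id), ]
  expect_equal(res$label, c("common", "est_supported", "novel", "common"))
  expect_equal(res$extension[1], "both_ends")
  # minus-strand reference: left extension is 3', right is 5'
  expect_equal(res$extension[4], "both_ends")
  d5 <- map_to_reference(
    make_ts(list(id = "d2", locus = "D2", strand = "-",
                 exons = list(c(20100, 20600)))), reference)
  expect_equal(d5$extension, "5p_only")
})

test_that("anatomy statistics match a per-base oracle", {
  ts <- make_ts(
    list(id = "t1", locus = "L1", biotype = "coding",
         exons = list(c(0, 100), c(200, 300))),
    list(id = "t2", locus = "L1", biotype = "coding",
         exons = list(c(50, 150))),
    list(id = "m", locus = "L2", biotype = "lncRNA",
         exons = list(c(1000, 1400))))
  st <- anatomy_stats(ts, c(chr1 = 10000))
  cod <- st[st$biotype == "coding", ]
  expect_equal(cod$mean_intron_length, 100)
  expect_equal(cod$mono_exonic_fraction, 0.5)
  ex <- ts$exons[ts$exons$transcript_id %in% c("t1", "t2"), ]
  expect_equal(cod$transcribed_fraction, brute_covered_bases(ex) / 10000)
  lnc <- st[st$biotype == "lncRNA", ]
  expect_true(is.na(lnc$mean_intron_length))
  expect_equal(lnc$mean_exon_count, 1)
})

test_that("the cascade is monotone and recovers planted truth", {
  ds <- simulate_dataset(small_config(seed = 12))
  cls <- classify_transcripts(ds$models, ds$annotation, cage = ds$cage)
  res <- cls$results
  stage_rank <- c(discarded_short = 0, coding = 1, candidate = 2,
                  potential = 3, lncRNA = 4, lincRNA = 5)
  # lincRNA implies lncRNA implies potential implies candidate
  linc_ids <- cls$lincRNAs$transcripts$transcript_id
  lnc_ids <- cls$lncRNAs$transcripts$transcript_id
  expect_true(all(linc_ids %in% lnc_ids))
  expect_true(all(stage_rank[res$stage_reached[
    res$transcript_id %in% lnc_ids]] >= 4))
  # every non-lncRNA outcome carries a reason
  not_lnc <- res[!(res$transcript_id %in% lnc_ids), ]
  expect_true(all(nzchar(not_lnc$filter_reasons)))
  # planted positional violations that reach the positional stage are
  # removed for the planted reason family
  tr <- ds$truth
  rr <- stats::setNames(res$filter_reasons, res$transcript_id)
  st <- stats::setNames(res$stage_reached, res$transcript_id)
  for (tid in names(tr$violations)) {
    expect_false(st[[tid]] %in% c("lncRNA", "lincRNA"))
    if (st[[tid]] == "potential") {
      expected <- switch(tr$violations[[tid]],
        mono_overlap = "mono_exonic_overlaps_coding",
        mono_downstream = "mono_exonic_downstream_of_coding",
        sense_overlap = "same_strand_overlaps_coding",
        sense_downstream = "same_strand_downstream_of_coding")
      expect_equal(unname(rr[[tid]]), expected)
    }
  }
  # antisense genic placements that survive NCP are lncRNA but not lincRNA
  genic <- tr$genic_antisense
  surv <- genic[st[genic] %in% c("lncRNA", "lincRNA")]
  expect_true(all(st[surv] == "lncRNA"))
  # recall of planted clean lincRNAs is high and nothing false comes in
  truth_linc <- names(tr$biotype)[tr$biotype == "lincRNA"]
  expect_gt(length(intersect(linc_ids, truth_linc)) / length(truth_linc), 0.8)
  expect_equal(length(setdiff(linc_ids, truth_linc)), 0)
})
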