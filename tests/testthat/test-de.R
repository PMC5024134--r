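test_that("CPM is the library-size-scaled count", {
  m <- matrix(c(5L, 0L, 10L, 0L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cm <- count_matrix(m, c(1e6, 2e6))
  x <- cpm(cm)
  expect_equal(x["a", "s1"], 5)
  expect_equal(x["a", "s2"], 5)
  expect_equal(unname(x["b", ]), c(0, 0))
  cm2 <- count_matrix(2L * m, 2 * c(1e6, 2e6))
  expect_equal(cpm(cm2), x)
  expect_equal(unname(pooled_cpm(cm)), c(15 / 3, 0))
})

test_that("housekeeping selection follows the pooled-CPM/SD/SwissProt walk", {
  # 100 quiet SwissProt genes spanning 305 transcripts, plus noisy genes,
  # a low-expression transcript and non-SwissProt quiet genes
  set.seed(1)
  n_per_gene <- c(rep(3, 95), rep(4, 5))            # 305 transcripts
  ids <- unlist(lapply(seq_along(n_per_gene), function(g)
    sprintf("hk%03d_t%d", g, seq_len(n_per_gene[g]))))
  genes <- sub("_t\\d+$", "", ids)
  quiet <- matrix(rep(100 + seq_along(ids) %% 7, 3), ncol = 3)
  noisy_ids <- sprintf("ns%03d_t1", 1:40)
  noisy <- matrix(rep(c(1000, 50, 2000), each = 40), ncol = 3) +
    matrix(rpois(120, 20), ncol = 3)
  nosp_ids <- sprintf("np%03d_t1", 1:10)
  nosp <- matrix(50, 10, 3)
  low_ids <- "low_t1"
  low <- matrix(c(0, 1, 0), 1)                       # pooled CPM < 1
  counts <- rbind(quiet, noisy, nosp, low)
  rownames(counts) <- c(ids, noisy_ids, nosp_ids, low_ids)
  colnames(counts) <- c("egg", "epi30", "hpf24")
  cm <- count_matrix(counts, rep(1e6, 3))
  ann <- data.frame(
    transcript_id = rownames(counts),
    has_swissprot_hit = !(rownames(counts) %in% nosp_ids))
  loci <- stats::setNames(sub("_t\\d+$", "", rownames(counts)),
                          rownames(counts))
  hk <- select_housekeeping(cm, ann, loci, n_genes = 100)
  expect_length(hk$housekeeping_gene_ids, 100)
  expect_length(hk$housekeeping_transcript_ids, 305)
  expect_setequal(hk$housekeeping_gene_ids, unique(genes))
  expect_false(low_ids %in% hk$housekeeping_transcript_ids)
  expect_false(any(nosp_ids %in% hk$housekeeping_transcript_ids))
  # a shortfall of eligible genes is an explicit error
  expect_error(select_housekeeping(cm, ann, loci, n_genes = 150),
               "eligible genes")
})

test_that("dispersion estimation hits the Poisson floor on Poisson data", {
  set.seed(2)
  y <- matrix(rpois(900, 200), ncol = 3,
              dimnames = list(sprintf("t%03d", 1:300), c("a", "b", "c")))
  cm <- count_matrix(y, rep(sum(y) / 3, 3))
  phi <- estimate_dispersion(cm)
  expect_lt(as.numeric(phi), 0.01)
})

test_that("dispersion estimation recovers the generating phi", {
  set.seed(3)
  est <- vapply(1:20, function(i) {
    y <- matrix(rnbinom(305 * 3, mu = 150, size = 1 / 0.35), ncol = 3,
                dimnames = list(sprintf("t%03d", 1:305), c("a", "b", "c")))
    as.numeric(estimate_dispersion(count_matrix(y, rep(1e6, 3))))
  }, 0)
  expect_lt(abs(mean(est) - 0.35), 0.1)
})

test_that("exact test matches closed forms and the brute-force oracle", {
  expect_equal(nb_exact_test(0, 0, phi = 0.35), 1)
  expect_equal(nb_exact_test(10, 0, phi = 0), 2 * 0.5^10)
  for (phi in c(0, 0.35, 1)) {
    for (s in c(1, 2, 3, 5, 10, 50)) {
      for (y1 in 0:s) {
        expect_equal(nb_exact_test(y1, s - y1, phi = phi),
                     brute_nb_exact(y1, s - y1, phi), tolerance = 1e-10)
      }
    }
  }
  # mildly unequal libraries use the analytic conditional
  p <- nb_exact_test(30, 25, lib1 = 1e6, lib2 = 0.95e6, phi = 0.35)
  expect_equal(p, brute_nb_exact(30, 25, 0.35, 1e6, 0.95e6),
               tolerance = 1e-10)
  expect_error(nb_exact_test(-1, 2, phi = 0.1), "non-negative")
})

test_that("exact test agrees with an established reference implementation", {
  library(edgeR)
  cases <- rbind(c(800, 100), c(35, 20), c(5, 0), c(150, 150))
  for (phi in c(0.05, 0.35)) {
    for (i in seq_len(nrow(cases))) {
      d <- edgeR::DGEList(counts = matrix(cases[i, ], 1, 2),
                          group = c(1, 2), lib.size = c(1e6, 1e6))
      ref <- edgeR::exactTest(d, dispersion = phi)$table$PValue
      expect_equal(nb_exact_test(cases[i, 1], cases[i, 2], phi = phi), ref,
                   tolerance = 1e-8)
    }
  }
})

test_that("run_de filters, thresholds, and keeps swap symmetry", {
  set.seed(4)
  counts <- matrix(rnbinom(300, mu = 100, size = 1 / 0.1), ncol = 3)
  rownames(counts) <- sprintf("t%03d", seq_len(nrow(counts)))
  colnames(counts) <- c("egg", "epi30", "hpf24")
  counts["t001", ] <- c(0L, 0L, 0L)        # max CPM 0 -> excluded
  counts["t002", ] <- c(4000L, 1100L, 100L) # |logFC| < 2 vs epi30
  cm <- count_matrix(counts, rep(1e6, 3))
  de <- run_de(cm, phi = 0.1)
  expect_false("t001" %in% de$transcript_id)
  r <- de[de$transcript_id == "t002" & de$comparison == "egg_vs_epi30", ]
  expect_lt(r$logFC, 2)
  expect_equal(r$call, "ns")
  # fdr column is BH within comparison
  d1 <- de[de$comparison == "egg_vs_epi30", ]
  expect_equal(d1$fdr, stats::p.adjust(d1$p_value, method = "BH"))
  # swapping the stages flips logFC and preserves p
  fwd <- run_de(cm, phi = 0.1, comparisons = list(c("egg", "epi30")))
  rev <- run_de(cm, phi = 0.1, comparisons = list(c("epi30", "egg")))
  expect_equal(fwd$logFC, -rev$logFC)
  expect_equal(fwd$p_value, rev$p_value)
})

test_that("a strong fold change below the logFC floor stays non-significant", {
  cm <- count_matrix(matrix(c(3800L, 1000L), 1, 2,
                            dimnames = list("t", c("a", "b"))), rep(1e6, 2))
  de <- run_de(cm, phi = 0, comparisons = list(c("a", "b")))
  expect_lt(de$p_value, 1e-10)
  expect_lt(de$logFC, 2)
  expect_equal(de$call, "ns")
})

test_that("stage-specific classification needs both egg comparisons", {
  mk <- function(id, c1, c2) data.frame(
    transcript_id = id,
    comparison = c("egg_vs_epi30", "egg_vs_hpf24"),
    stage_a = "egg", stage_b = c("epi30", "hpf24"),
    logFC = 0, p_value = 1, fdr = 1, call = c(c1, c2))
  de <- rbind(mk("both_up", "up", "up"), mk("one_up", "up", "ns"),
              mk("both_down", "down", "down"), mk("mixed", "up", "down"))
  ss <- classify_stage_specific(de)
  expect_equal(ss$maternal, "both_up")
  expect_equal(ss$embryonic, "both_down")
  expect_length(intersect(ss$maternal, ss$embryonic), 0)
  expect_error(classify_stage_specific(de[de$comparison == "egg_vs_epi30", ]),
               "both egg comparisons")
})

test_that("neighbour fold-change correlation matches the rank formula", {
  lnc <- make_ts(list(id = "l1", exons = list(c(1000, 1500))),
                 list(id = "l2", exons = list(c(50000, 50500))),
                 list(id = "l3", exons = list(c(100000, 100500))),
                 list(id = "l4", exons = list(c(150000, 150500))),
                 list(id = "l5", exons = list(c(200000, 200500))))
  cod <- make_ts(list(id = "g1", exons = list(c(2000, 2500)), biotype = "coding"),
                 list(id = "g2", exons = list(c(51000, 51500)), biotype = "coding"),
                 list(id = "g3", exons = list(c(101000, 101500)), biotype = "coding"),
                 list(id = "g4", exons = list(c(151000, 151500)), biotype = "coding"),
                 list(id = "g5", exons = list(c(201000, 201500)), biotype = "coding"))
  fc <- c(l1 = 0.3, l2 = -1, l3 = 2, l4 = 0.5, l5 = -2,
          g1 = 0.1, g2 = -0.5, g3 = 1.4, g4 = 0.2, g5 = -1.2)
  de <- data.frame(transcript_id = names(fc), comparison = "egg_vs_epi30",
                   stage_a = "egg", stage_b = "epi30", logFC = unname(fc),
                   p_value = 0.5, fdr = 0.5, call = "ns")
  res <- neighbor_fc_correlation(de, lnc, cod)
  expect_equal(res$n_pairs, 5)
  expect_equal(res$rho,
               cor(fc[paste0("l", 1:5)], fc[paste0("g", 1:5)],
                   method = "spearman"))
  expect_equal(res$rho, 1 - 6 * sum((rank(fc[1:5]) - rank(fc[6:10]))^2) /
                 (5 * 24))
  # perfectly co-varying and rank-reversed toy cases
  de2 <- de; de2$logFC[6:10] <- de2$logFC[1:5]
  expect_equal(neighbor_fc_correlation(de2, lnc, cod)$rho, 1)
  de3 <- de; de3$logFC[6:10] <- -de3$logFC[1:5]
  expect_equal(neighbor_fc_correlation(de3, lnc, cod)$rho, -1)
})

test_that("fpkm aggregates to gene-level mean expression", {
  m <- matrix(c(100L, 300L, 100L, 300L), 2,
              dimnames = list(c("g1_t1", "g1_t2"), c("a", "b")))
  cm <- count_matrix(m, c(1e6, 1e6))
  f <- fpkm(cm, c(g1_t1 = 1000, g1_t2 = 1000))
  expect_equal(unname(f[, "a"]), c(100, 300))
  g <- fpkm(cm, c(g1_t1 = 1000, g1_t2 = 1000),
            loci = c(g1_t1 = "g1", g1_t2 = "g1"))
  expect_equal(unname(g["g1", ]), c(200, 200))
})
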