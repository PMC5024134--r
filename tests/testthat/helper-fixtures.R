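# compact transcript_set builder: each spec is
# list(id, exons = list(c(start, end), ...), chrom, strand, locus, biotype)
make_ts <- function(...) {
  specs <- list(...)
  one <- function(s, default) if (is.null(s)) default else s
  tx <- do.call(rbind, lapply(specs, function(s) data.frame(
    transcript_id = s$id,
    locus_id = one(s$locus, s$id),
    chrom = one(s$chrom, "chr1"),
    strand = one(s$strand, "+"),
    biotype = one(s$biotype, "unclassified"),
    stringsAsFactors = FALSE)))
  ex <- do.call(rbind, lapply(specs, function(s) data.frame(
    transcript_id = s$id,
    chrom = one(s$chrom, "chr1"),
    start = vapply(s$exons, `[`, 0, 1),
    end = vapply(s$exons, `[`, 0, 2),
    strand = one(s$strand, "+"),
    stringsAsFactors = FALSE)))
  transcript_set(tx, ex)
}

# small, fast simulation used across tests
small_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    genome = stats::setNames(rep(500000, 8), sprintf("chr%d", 1:8)),
    n_coding = 150, n_lncRNA = 40, n_decoy = 25, n_short = 3,
    n_housekeeping_true = 20,
    n_planted_syntenic = 5, n_planted_conserved = 3,
    n_background_blocks = 30,
    n_te_lnc_loci = 4, n_te_coding_loci = 6,
    n_tss_ltr_lnc = 2, n_tss_ltr_coding = 3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# per-base coverage oracle: total covered bases of an interval set
brute_covered_bases <- function(intervals, chrom_len = 10000) {
  total <- 0
  for (chrom in unique(intervals$chrom)) {
    cov <- logical(chrom_len)
    d <- intervals[intervals$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(d))) cov[(d$start[i] + 1):d$end[i]] <- TRUE
    total <- total + sum(cov)
  }
  total
}

# brute-force conditional NB exact test via dnbinom (independent of the
# lchoose-based implementation path)
brute_nb_exact <- function(y1, y2, phi, lib1 = 1, lib2 = 1, mu = 7) {
  s <- y1 + y2
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    w <- stats::dpois(k, mu * lib1) * stats::dpois(s - k, mu * lib2)
  } else {
    rel <- c(lib1, lib2) / mean(c(lib1, lib2))
    # common success probability cancels in the conditional
    w <- stats::dnbinom(k, size = rel[1] / phi, prob = 0.3) *
      stats::dnbinom(s - k, size = rel[2] / phi, prob = 0.3)
  }
  w <- w / sum(w)
  min(1, sum(w[w <= w[y1 + 1] * (1 + 1e-12)]))
}

# exhaustive microsynteny evaluation straight from the definition
brute_pairwise_synteny <- function(lincs1, coding1, lincs2, coding2,
                                   orthology) {
  s1 <- locus_spans(coding1)
  s2 <- locus_spans(coding2)
  tx1 <- lincs1$transcripts
  tx2 <- lincs2$transcripts
  ok <- paste(orthology$gene_a, orthology$gene_b)
  out <- list()
  for (i in seq_len(nrow(tx1))) for (j in seq_len(nrow(tx2))) {
    f1 <- flanking_genes(tx1[i, ], s1)
    f2 <- flanking_genes(tx2[j, ], s2)
    hit <- FALSE
    for (ga in c(f1$upstream, f1$downstream))
      for (gb in c(f2$upstream, f2$downstream))
        if (!is.na(ga) && !is.na(gb) && paste(ga, gb) %in% ok) hit <- TRUE
    if (hit) out[[length(out) + 1]] <-
        data.frame(linc_a = tx1$transcript_id[i],
                   linc_b = tx2$transcript_id[j], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(linc_a = character(), linc_b = character()))
  res <- do.call(rbind, out)
  res[order(res$linc_a, res$linc_b), , drop = FALSE]
}

# hypergeometric over-representation tail computed by direct summation
brute_hyper_p <- function(k, n_set, K, N) {
  i <- k:min(n_set, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n_set - i) - lchoose(N, n_set)))
}
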