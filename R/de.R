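#' Counts per million mapped reads
#'
#' @param cm a [count_matrix()]
#' @return numeric matrix: `counts[t, s] / library_sizes[s] * 1e6`
#' @export
cpm <- function(cm) {
  if (any(cm$library_sizes <= 0)) stop("library sizes must be positive")
  sweep(cm$counts, 2, cm$library_sizes, "/") * 1e6
}

#' Pooled CPM over all stages
#'
#' Expression pooled over the experiment: summed counts over all stages
#' divided by the summed library sizes, per million.
#' @param cm a [count_matrix()]
#' @return named numeric vector per transcript
#' @export
pooled_cpm <- function(cm) {
  rowSums(cm$counts) / sum(cm$library_sizes) * 1e6
}

#' Select housekeeping transcripts for dispersion inference
#'
#' The replicate-free strategy: (1) discard transcripts with pooled CPM
#' below `min_pooled_cpm`; (2) rank the survivors by the standard deviation
#' of their per-stage CPM; (3) discard transcripts of genes without a
#' SwissProt match; (4) walking up the SD ranking, collect genes until
#' `n_genes` distinct genes are reached; the housekeeping set is all
#' surviving transcripts of those genes.
#'
#' @param cm a [count_matrix()]
#' @param annotation data.frame with `transcript_id` and `has_swissprot_hit`
#' @param loci named character vector mapping transcript_id -> locus (gene) id
#' @param n_genes number of housekeeping genes to collect (default 100)
#' @param min_pooled_cpm pooled-CPM floor (default 1; transcripts strictly
#'   below are discarded)
#' @return list with `housekeeping_gene_ids` and `housekeeping_transcript_ids`
#' @export
select_housekeeping <- function(cm, annotation, loci, n_genes = 100,
                                min_pooled_cpm = 1) {
  ids <- rownames(cm$counts)
  keep <- pooled_cpm(cm) >= min_pooled_cpm
  x <- cpm(cm)[keep, , drop = FALSE]
  ids <- ids[keep]
  sds <- apply(x, 1, stats::sd)
  sp <- stats::setNames(annotation$has_swissprot_hit, annotation$transcript_id)
  gene <- unname(loci[ids])
  gene_has_sp <- tapply(sp[ids], gene, any)
  ok <- !is.na(gene) & gene_has_sp[gene]
  ids <- ids[ok]; sds <- sds[ok]; gene <- gene[ok]
  if (length(unique(gene)) < n_genes)
    stop("only ", length(unique(gene)), " eligible genes; ", n_genes,
         " housekeeping genes requested")
  ord <- order(sds, ids)
  first_gene <- unique(gene[ord])
  chosen <- first_gene[seq_len(n_genes)]
  hk <- ids[gene %in% chosen]
  list(housekeeping_gene_ids = chosen, housekeeping_transcript_ids = hk)
}

# restore-RNG helper: run expr with a private seed
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Thin counts to a common library size
#'
#' Binomial downsampling of each stage's counts to the smallest library
#' size, the stochastic library equalisation used when stage depths differ
#' substantially. Deterministic given `seed`.
#'
#' @param cm a [count_matrix()]
#' @param seed integer seed for the thinning draws
#' @return a [count_matrix()] with equal library sizes
#' @export
thin_to_common_depth <- function(cm, seed = 1) {
  target <- min(cm$library_sizes)
  out <- cm$counts
  .with_seed(seed, {
    for (j in seq_len(ncol(out))) {
      pr <- target / cm$library_sizes[j]
      if (pr < 1) out[, j] <- stats::rbinom(nrow(out), out[, j], pr)
    }
  })
  count_matrix(out, rep(target, ncol(out)))
}

# conditional log-probabilities of splitting a total s into counts with NB
# size parameters r (length = n groups): negative-hypergeometric family.
# Returns the log weight of one configuration y (vector summing to s).
.nh_logprob <- function(y, r) {
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1)) -
    (lgamma(sum(y) + sum(r)) - lgamma(sum(r)) - lgamma(sum(y) + 1))
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Estimates a single dispersion phi (variance `mu + phi mu^2`) shared by a
#' set of transcripts, treating the stages as replicates: for each
#' transcript the likelihood of its counts conditional on their total is a
#' negative-hypergeometric distribution that depends only on phi (the
#' unknown per-transcript mean cancels). Library sizes are equalised first
#' (binomial thinning) when they differ by more than `thin_threshold`;
#' smaller imbalances are absorbed by per-stage size parameters
#' proportional to library size.
#'
#' @param cm a [count_matrix()] restricted to the transcripts to use
#'   (typically the housekeeping set)
#' @param interval search interval for phi (default `c(1e-6, 10)`)
#' @param thin_threshold maximum tolerated library-size ratio before
#'   thinning (default 1.1)
#' @param thin_seed seed for the thinning draws
#' @return the estimated dispersion (numeric scalar) with attribute
#'   `"logLik"`
#' @export
estimate_dispersion <- function(cm, interval = c(1e-6, 10),
                                thin_threshold = 1.1, thin_seed = 1) {
  if (ncol(cm$counts) < 2) stop("need >= 2 stages to estimate dispersion")
  ratio <- max(cm$library_sizes) / min(cm$library_sizes)
  if (ratio > thin_threshold) cm <- thin_to_common_depth(cm, thin_seed)
  y <- cm$counts
  rel <- cm$library_sizes / mean(cm$library_sizes)
  s <- rowSums(y)
  use <- s > 0
  y <- y[use, , drop = FALSE]
  s <- s[use]
  if (!nrow(y)) stop("all-zero count matrix: dispersion not estimable")
  negll <- function(phi) {
    r <- rel / phi
    R <- sum(r)
    ll <- sum(lgamma(sweep(y, 2, r, "+")) - rep(lgamma(r), each = nrow(y)) -
                lgamma(y + 1)) +
      sum(-(lgamma(s + R) - lgamma(R) - lgamma(s + 1)))
    -ll
  }
  opt <- stats::optimize(negll, interval = interval)
  if (!is.finite(opt$objective))
    stop("dispersion optimisation failed (non-finite likelihood); ",
         "library sizes: ", paste(cm$library_sizes, collapse = ", "))
  phi <- opt$minimum
  attr(phi, "logLik") <- -opt$objective
  phi
}

#' Conditional negative-binomial exact test for a single pair of counts
#'
#' The replicate-free two-sample exact test: conditional on the total
#' `s = y1 + y2`, each split follows a negative-hypergeometric distribution
#' determined by the dispersion alone (Binomial(s, N1/(N1+N2)) in the
#' Poisson limit `phi = 0`). The two-sided p-value sums the probabilities of
#' all outcomes no more likely than the observed one, capped at 1. Library
#' sizes within `thin_threshold` of each other enter through per-sample
#' size parameters proportional to depth; larger imbalances are equalised by
#' binomial thinning of the deeper sample (deterministic given `thin_seed`).
#'
#' @param y1,y2 observed counts (non-negative integers)
#' @param lib1,lib2 library sizes (default equal)
#' @param phi common dispersion (>= 0; 0 gives the Poisson/binomial limit)
#' @param thin_threshold,thin_seed library equalisation controls
#' @return two-sided p-value in (0, 1]
#' @export
nb_exact_test <- function(y1, y2, lib1 = 1, lib2 = 1, phi = 0,
                          thin_threshold = 1.1, thin_seed = 1) {
  if (y1 < 0 || y2 < 0 || y1 != round(y1) || y2 != round(y2))
    stop("counts must be non-negative integers")
  if (phi < 0) stop("phi must be >= 0")
  ratio <- max(lib1, lib2) / min(lib1, lib2)
  if (ratio > thin_threshold) {
    target <- min(lib1, lib2)
    .with_seed(thin_seed, {
      if (lib1 > target) y1 <- stats::rbinom(1, y1, target / lib1)
      if (lib2 > target) y2 <- stats::rbinom(1, y2, target / lib2)
    })
    lib1 <- lib2 <- target
  }
  s <- y1 + y2
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    lw <- stats::dbinom(k, s, lib1 / (lib1 + lib2), log = TRUE)
  } else {
    rel <- c(lib1, lib2) / mean(c(lib1, lib2))
    r <- rel / phi
    lw <- lgamma(k + r[1]) - lgamma(k + 1) +
      lgamma(s - k + r[2]) - lgamma(s - k + 1)
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  w <- w / sum(w)
  min(1, sum(w[w <= w[y1 + 1] * (1 + 1e-12)]))
}

#' Replicate-free differential expression across stage pairs
#'
#' Runs the conditional exact test for every ordered pair of stages on all
#' transcripts passing the per-stage CPM filter, applies Benjamini-Hochberg
#' FDR within each comparison, and calls transcripts up/down when both the
#' FDR and the absolute log2 fold change pass their thresholds. Fold changes
#' are computed from library-size-normalised counts with a pseudo-count of
#' `pseudo_cpm` (per million) on each side; `call = "up"` means higher in
#' the first stage of the comparison.
#'
#' @param cm a [count_matrix()]
#' @param phi common dispersion for the exact test
#' @param min_cpm per-stage CPM filter: transcripts with CPM >
#'   `min_cpm` in at least one stage are tested (default 0.5, strict)
#' @param fdr_max,min_abs_logfc significance thresholds (defaults 0.01 and
#'   2, both compared inclusively)
#' @param pseudo_cpm pseudo-count on the CPM scale (default 0.25)
#' @param comparisons optional list of 2-vectors of stage names; default all
#'   ordered pairs in column order
#' @return data.frame with columns `transcript_id`, `comparison`, `stage_a`,
#'   `stage_b`, `logFC`, `p_value`, `fdr`, `call`
#' @export
run_de <- function(cm, phi, min_cpm = 0.5, fdr_max = 0.01, min_abs_logfc = 2,
                   pseudo_cpm = 0.25, comparisons = NULL,
                   thin_threshold = 1.1, thin_seed = 1) {
  x <- cpm(cm)
  keep <- apply(x, 1, max) > min_cpm
  counts <- cm$counts[keep, , drop = FALSE]
  x <- x[keep, , drop = FALSE]
  # library equalisation for the conditional test happens once at matrix
  # level (independent thinning per cell); fold changes stay on the
  # CPM scale of the original libraries
  test_libs <- cm$library_sizes
  if (max(test_libs) / min(test_libs) > thin_threshold) {
    eq <- thin_to_common_depth(count_matrix(counts, test_libs), thin_seed)
    test_counts <- eq$counts
    test_libs <- eq$library_sizes
  } else test_counts <- counts
  stages <- colnames(counts)
  if (is.null(comparisons)) {
    comparisons <- list()
    for (i in seq_along(stages)) for (j in seq_along(stages))
      if (i < j) comparisons[[length(comparisons) + 1]] <- c(stages[i], stages[j])
  }
  out <- lapply(comparisons, function(cmp) {
    a <- cmp[1]; b <- cmp[2]
    p <- vapply(seq_len(nrow(test_counts)), function(i)
      nb_exact_test(test_counts[i, a], test_counts[i, b],
                    test_libs[a], test_libs[b], phi), 0)
    lfc <- log2((x[, a] + pseudo_cpm) / (x[, b] + pseudo_cpm))
    fdr <- stats::p.adjust(p, method = "BH")
    call <- rep("ns", length(p))
    sig <- fdr <= fdr_max & abs(lfc) >= min_abs_logfc
    call[sig & lfc > 0] <- "up"
    call[sig & lfc < 0] <- "down"
    data.frame(transcript_id = rownames(counts),
               comparison = paste0(a, "_vs_", b), stage_a = a, stage_b = b,
               logFC = unname(lfc), p_value = p, fdr = fdr, call = call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify maternal and embryonic specific transcripts
#'
#' Maternal transcripts are significantly up in the egg stage in both
#' comparisons involving the egg; embryonic transcripts are significantly
#' down in the egg in both. All comparisons with the egg stage first must be
#' present in the DE table.
#'
#' @param de output of [run_de()]
#' @param egg_stage name of the egg (maternal) stage, default `"egg"`
#' @return list with character vectors `maternal` and `embryonic`
#' @export
classify_stage_specific <- function(de, egg_stage = "egg") {
  egg <- de[de$stage_a == egg_stage, , drop = FALSE]
  cmps <- unique(egg$comparison)
  if (length(cmps) < 2)
    stop("need both egg comparisons; found: ", paste(cmps, collapse = ", "))
  up_all <- tapply(egg$call == "up", egg$transcript_id, all)
  dn_all <- tapply(egg$call == "down", egg$transcript_id, all)
  n_cmp <- tapply(egg$comparison, egg$transcript_id, function(x)
    length(unique(x)))
  full <- names(n_cmp)[n_cmp == length(cmps)]
  list(maternal = sort(names(up_all)[up_all & names(up_all) %in% full]),
       embryonic = sort(names(dn_all)[dn_all & names(dn_all) %in% full]))
}

#' Correlation of lncRNA and proximal coding-gene fold changes
#'
#' Pairs each lncRNA with the coding transcripts whose spans lie within
#' `window` bp of its own span and computes the Spearman rank correlation of
#' their log2 fold changes, pooled over the DE comparisons; the p-value uses
#' the large-sample t approximation.
#'
#' @param de output of [run_de()] covering both sets
#' @param lncrnas,coding `transcript_set`s of the two populations
#' @param window pairing distance in bp (default 10000)
#' @return list with `rho`, `p`, `n_pairs` and the `pairs` data.frame
#' @export
neighbor_fc_correlation <- function(de, lncrnas, coding, window = 10000) {
  pairs <- window_pairs(lncrnas$transcripts, coding$transcripts, window)
  pairs <- pairs[pairs$query != pairs$subject, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no lncRNA/coding pairs within window")
  per_cmp <- split(de, de$comparison)
  pts <- do.call(rbind, lapply(per_cmp, function(d) {
    fc <- stats::setNames(d$logFC, d$transcript_id)
    data.frame(comparison = d$comparison[1],
               lnc = pairs$query, gene = pairs$subject,
               lnc_fc = unname(fc[pairs$query]),
               gene_fc = unname(fc[pairs$subject]),
               stringsAsFactors = FALSE)
  }))
  pts <- pts[stats::complete.cases(pts$lnc_fc, pts$gene_fc), , drop = FALSE]
  if (nrow(pts) < 3) stop("fewer than 3 fold-change pairs available")
  ct <- suppressWarnings(stats::cor.test(pts$lnc_fc, pts$gene_fc,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(pts),
       pairs = pts)
}

#' FPKM and gene-level expression aggregation
#'
#' Helper for gene-level comparisons: fragments per kilobase of transcript
#' per million mapped reads, and the mean FPKM over all transcripts of a
#' gene as that gene's expression level.
#'
#' @param cm a [count_matrix()]
#' @param lengths named numeric vector of transcript lengths in nt
#' @param loci optional named vector transcript_id -> locus id; when given,
#'   a gene-level matrix of mean FPKM is returned
#' @return FPKM matrix, or gene-level mean-FPKM matrix when `loci` is given
#' @export
fpkm <- function(cm, lengths, loci = NULL) {
  len <- lengths[rownames(cm$counts)]
  f <- sweep(cm$counts, 2, cm$library_sizes / 1e6, "/") / (len / 1000)
  if (is.null(loci)) return(f)
  g <- unname(loci[rownames(f)])
  rs <- rowsum(f, g)
  rs / as.numeric(table(g)[rownames(rs)])
}
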