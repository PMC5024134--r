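#' Immediate flanking coding genes of an intergenic lncRNA
#'
#' The nearest coding gene lying entirely to the chromosomal left
#' (upstream) and right (downstream) of the lincRNA span. Ties (two genes
#' ending, or starting, at the same coordinate) are broken by the
#' lexicographically smaller locus id.
#'
#' @param linc single-row data.frame with `chrom`, `start`, `end` (a row of
#'   a `transcript_set` transcript table)
#' @param coding_spans data.frame of coding locus spans
#'   (see [locus_spans()])
#' @return list with `upstream` and `downstream` locus ids (`NA` when the
#'   lincRNA is first/last on its chromosome)
#' @export
flanking_genes <- function(linc, coding_spans) {
  g <- coding_spans[coding_spans$chrom == linc$chrom, , drop = FALSE]
  left <- g[g$end <= linc$start, , drop = FALSE]
  right <- g[g$start >= linc$end, , drop = FALSE]
  up <- if (nrow(left)) {
    left <- left[order(-left$end, left$locus_id), , drop = FALSE]
    left$locus_id[1]
  } else NA_character_
  down <- if (nrow(right)) {
    right <- right[order(right$start, right$locus_id), , drop = FALSE]
    right$locus_id[1]
  } else NA_character_
  list(upstream = up, downstream = down)
}

# internal: flank table for all lincRNAs of one species (vectorised
# equivalent of flanking_genes applied row-wise, including its tie-break)
.flank_table <- function(lincs, coding) {
  spans <- if (is.data.frame(coding)) coding else locus_spans(coding)
  tx <- lincs$transcripts
  out <- data.frame(transcript_id = tx$transcript_id, strand = tx$strand,
                    upstream = NA_character_, downstream = NA_character_,
                    upstream_strand = NA_character_,
                    downstream_strand = NA_character_,
                    stringsAsFactors = FALSE)
  for (chrom in unique(tx$chrom)) {
    g <- spans[spans$chrom == chrom, , drop = FALSE]
    li <- which(tx$chrom == chrom)
    if (!nrow(g)) next
    # upstream: greatest end <= linc start; ties -> smallest locus id
    ge <- g[order(g$end, g$locus_id), , drop = FALSE]
    idx <- findInterval(tx$start[li], ge$end)
    has <- idx >= 1
    first <- match(ge$end[pmax(idx, 1)], ge$end)   # first of the tie run
    out$upstream[li[has]] <- ge$locus_id[first[has]]
    out$upstream_strand[li[has]] <- ge$strand[first[has]]
    # downstream: smallest start >= linc end; ties -> smallest locus id
    gs <- g[order(g$start, g$locus_id), , drop = FALSE]
    idx2 <- findInterval(tx$end[li] - 0.5, gs$start) + 1
    has2 <- idx2 <= nrow(gs)
    out$downstream[li[has2]] <- gs$locus_id[idx2[has2]]
    out$downstream_strand[li[has2]] <- gs$strand[idx2[has2]]
  }
  out
}

#' Pairwise microsynteny calls between two species
#'
#' A pair of intergenic lncRNAs is microsyntenic when at least one of the
#' immediate flanking coding genes of one is orthologous to an immediate
#' flanking coding gene of the other. For each call the shared flank sides
#' are reported, and `orientation_conserved` is `TRUE` when some shared
#' orthologous flank lies on the same side of both lincRNAs and the two
#' lincRNAs have the same strand relative to that flanking gene.
#'
#' @param lincs1,coding1 `transcript_set`s for species 1
#' @param lincs2,coding2 `transcript_set`s for species 2
#' @param orthology data.frame with columns `gene_a` (species-1 locus ids)
#'   and `gene_b` (species-2 locus ids)
#' @return data.frame with one row per syntenic pair: `linc_a`, `linc_b`,
#'   `shared_flank`, `orientation_conserved`
#' @export
pairwise_synteny <- function(lincs1, coding1, lincs2, coding2, orthology) {
  f1 <- .flank_table(lincs1, coding1)
  f2 <- .flank_table(lincs2, coding2)
  sides <- c("upstream", "downstream")
  # long format: one row per (linc, side) with a flank present
  melt <- function(f) do.call(rbind, lapply(sides, function(s)
    data.frame(linc = f$transcript_id, side = s, gene = f[[s]],
               rel = f$strand == f[[paste0(s, "_strand")]],
               stringsAsFactors = FALSE)))
  m1 <- melt(f1); m1 <- m1[!is.na(m1$gene), , drop = FALSE]
  m2 <- melt(f2); m2 <- m2[!is.na(m2$gene), , drop = FALSE]
  # join linc1 flanks to linc2 flanks through the orthology map
  j1 <- merge(m1, orthology, by.x = "gene", by.y = "gene_a")
  hits <- merge(j1, m2, by.x = "gene_b", by.y = "gene",
                suffixes = c("_a", "_b"))
  if (!nrow(hits))
    return(data.frame(linc_a = character(), linc_b = character(),
                      shared_flank = character(),
                      orientation_conserved = logical()))
  hits$pair <- paste(hits$linc_a, hits$linc_b, sep = "\r")
  hits$flank <- paste0(hits$side_a, ":", hits$side_b)
  hits$orient <- hits$side_a == hits$side_b & hits$rel_a == hits$rel_b
  shared <- tapply(hits$flank, hits$pair, function(x)
    paste(sort(unique(x)), collapse = ","))
  orient <- tapply(hits$orient, hits$pair, any)
  pairs <- strsplit(names(shared), "\r", fixed = TRUE)
  out <- data.frame(linc_a = vapply(pairs, `[[`, "", 1),
                    linc_b = vapply(pairs, `[[`, "", 2),
                    shared_flank = unname(shared),
                    orientation_conserved = unname(orient[names(shared)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$linc_a, out$linc_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' lncRNAs microsyntenic across all species
#'
#' Given pairwise call tables among k species, returns per species the
#' lincRNAs that participate in a syntenic call with a lincRNA of every
#' other species.
#'
#' @param calls named list of pairwise call tables; names of the form
#'   `"sp1|sp2"` meaning `linc_a` belongs to `sp1` and `linc_b` to `sp2`
#' @param species character vector of all species
#' @return named list of transcript-id vectors per species
#' @export
multi_species_synteny <- function(calls, species) {
  out <- lapply(stats::setNames(species, species), function(sp) {
    partners <- setdiff(species, sp)
    per_partner <- lapply(partners, function(other) {
      key1 <- paste0(sp, "|", other)
      key2 <- paste0(other, "|", sp)
      ids <- character()
      if (key1 %in% names(calls)) ids <- c(ids, calls[[key1]]$linc_a)
      if (key2 %in% names(calls)) ids <- c(ids, calls[[key2]]$linc_b)
      unique(ids)
    })
    sort(Reduce(intersect, per_partner))
  })
  out
}

# observed statistic for the randomisation test: % of lincRNA-bearing
# intergenic regions whose lincRNA is microsyntenic across all species
.synteny_percent <- function(lincs_per_species, coding_per_species,
                             orthology_maps, species) {
  calls <- list()
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    a <- species[i]; b <- species[j]
    key <- paste0(a, "|", b)
    om <- orthology_maps[[key]]
    if (is.null(om)) om <- {
      rev <- orthology_maps[[paste0(b, "|", a)]]
      if (is.null(rev)) stop("no orthology map for ", key)
      data.frame(gene_a = rev$gene_b, gene_b = rev$gene_a)
    }
    calls[[key]] <- pairwise_synteny(lincs_per_species[[a]],
                                     coding_per_species[[a]],
                                     lincs_per_species[[b]],
                                     coding_per_species[[b]], om)
  }
  ms <- multi_species_synteny(calls, species)
  per_species <- vapply(species, function(sp) {
    ft <- .flank_table(lincs_per_species[[sp]], coding_per_species[[sp]])
    eligible <- ft$transcript_id[!(is.na(ft$upstream) & is.na(ft$downstream))]
    if (!length(eligible)) return(NA_real_)
    100 * length(intersect(ms[[sp]], eligible)) / length(eligible)
  }, 0)
  list(percent = mean(per_species, na.rm = TRUE), calls = calls,
       multi_species = ms, per_species = per_species)
}

#' Randomisation test for multi-species microsynteny
#'
#' Computes the observed percentage of lincRNA-bearing intergenic regions
#' that are microsyntenic across all species, then repeatedly shuffles the
#' lincRNA coordinates of every species (avoiding coding and lncRNA loci),
#' recomputing the percentage over the randomised intergenic regions. The
#' Z-score compares the observed value with the null mean and SD, with a
#' one-sided upper-tail normal p-value; when the null SD is zero the
#' add-one empirical p-value is reported and Z is `NA`.
#'
#' @param lincs_per_species,coding_per_species named lists of
#'   `transcript_set`s per species
#' @param orthology_maps named list of orthology tables, names `"sp1|sp2"`
#' @param genomes named list of chromosome-length vectors per species
#' @param n_reps number of randomisations (default 1000)
#' @param seed integer seed
#' @param exclude_per_species optional named list of extra exclusion
#'   intervals per species (coding locus spans are always excluded)
#' @return list with `observed`, `null_mean`, `null_sd`, `z`, `p`,
#'   `null` (the per-replicate percentages) and the observed `calls`
#' @export
synteny_randomization <- function(lincs_per_species, coding_per_species,
                                  orthology_maps, genomes, n_reps = 1000,
                                  seed = 1, exclude_per_species = NULL) {
  species <- names(lincs_per_species)
  coding_spans <- lapply(coding_per_species, locus_spans)
  obs <- .synteny_percent(lincs_per_species, coding_spans,
                          orthology_maps, species)
  excl_by_sp <- lapply(stats::setNames(species, species), function(sp) {
    extra <- if (!is.null(exclude_per_species))
      exclude_per_species[[sp]] else NULL
    merge_intervals(rbind(
      coding_spans[[sp]][, c("chrom", "start", "end")],
      lincs_per_species[[sp]]$transcripts[, c("chrom", "start", "end")],
      if (!is.null(extra)) extra[, c("chrom", "start", "end")]))
  })
  null <- vapply(seq_len(n_reps), function(r) {
    shuffled <- lapply(stats::setNames(species, species), function(sp)
      .with_seed(seed + r * length(species) + match(sp, species),
                 shuffle_transcripts(lincs_per_species[[sp]], genomes[[sp]],
                                     excl_by_sp[[sp]])))
    .synteny_percent(shuffled, coding_spans, orthology_maps,
                     species)$percent
  }, 0)
  mu <- mean(null)
  sdv <- stats::sd(null)
  if (n_reps >= 2 && sdv > 0) {
    z <- (obs$percent - mu) / sdv
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    z <- NA_real_
    p <- (1 + sum(null >= obs$percent)) / (1 + n_reps)
  }
  list(observed = obs$percent, null_mean = mu, null_sd = sdv, z = z, p = p,
       null = null, calls = obs$calls, multi_species = obs$multi_species)
}
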