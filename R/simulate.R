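#' Configuration for the synthetic developmental transcriptome
#'
#' Bundles every parameter of the generator with defaults emulating the
#' statistical structure of a compact-genome developmental RNA-seq study:
#' three stages (egg, 30% epiboly, 24 hpf), negative-binomial counts with a
#' common dispersion of 0.35, maternal transcripts 2^3-fold higher in the
#' egg (and embryonic the reverse), lncRNAs shorter, less spliced, with
#' longer exons and lower expression than coding transcripts, 100 planted
#' housekeeping genes, and planted conserved, microsyntenic and TE-bearing
#' features with recorded ground truth.
#'
#' @param seed integer master seed; every generator derives its own stream
#'   from it, so identical seeds give identical datasets
#' @param genome named vector of chromosome lengths (bp)
#' @param n_coding,n_lncRNA,n_decoy,n_short numbers of coding gene loci,
#'   lncRNA loci, non-coding-potential decoys (hitless short-ORF transcripts
#'   with coding-like composition) and sub-length transcripts
#' @param frac_maternal,frac_embryonic fractions of (non-housekeeping) loci
#'   with maternal / embryonic specific expression
#' @param logfc_magnitude log2 fold change between egg and later stages for
#'   stage-specific loci
#' @param dispersion_true common NB dispersion phi (variance mu + phi mu^2)
#' @param n_housekeeping_true number of constant-expression SwissProt genes
#' @param stage_effect_sd log2-scale SD of the stage wobble applied to
#'   stable non-housekeeping loci
#' @param frac_lnc_violation fraction of lncRNA loci deliberately placed to
#'   violate the positional filters (split evenly over the four removal
#'   modes)
#' @param frac_lnc_genic fraction placed as multi-exonic antisense overlaps
#'   of coding genes (retained lncRNAs that are not lincRNAs)
#' @param cage_frac named fractions of coding / lncRNA transcripts given a
#'   supporting CAGE tag
#' @param n_planted_syntenic,n_planted_conserved,n_background_blocks
#'   planted microsyntenic lincRNA pairs, conserved lncRNA pairs, and
#'   intergenic background alignment blocks per species
#' @param n_te_lnc_loci,n_te_coding_loci,n_tss_ltr_lnc,n_tss_ltr_coding,te_background_per_mb
#'   transposable-element planting controls
#' @param species names of the two simulated species (the first is the
#'   focal species carrying counts, CAGE, repeats and annotation)
#' @param ... further overrides of the remaining structural parameters
#'   (exon/intron/intergap log-normal parameters, expression log-normals,
#'   `stages`, `depth_range`, `n_go_terms`, `marker_go`, `min_length`)
#' @return a list of class `sim_config`
#' @export
simulation_config <- function(seed = 1,
                              genome = stats::setNames(rep(750000, 16),
                                                       sprintf("chr%d", 1:16)),
                              n_coding = 800, n_lncRNA = 250, n_decoy = 150,
                              n_short = 5,
                              frac_maternal = 0.06, frac_embryonic = 0.15,
                              logfc_magnitude = 3, dispersion_true = 0.35,
                              n_housekeeping_true = 100, stage_effect_sd = 0.8,
                              frac_lnc_violation = 0.16, frac_lnc_genic = 0.04,
                              cage_frac = c(coding = 0.57, lncRNA = 0.85),
                              n_planted_syntenic = 20, n_planted_conserved = 8,
                              n_background_blocks = 120,
                              n_te_lnc_loci = 12, n_te_coding_loci = 20,
                              n_tss_ltr_lnc = 5, n_tss_ltr_coding = 8,
                              te_background_per_mb = 15,
                              species = c("spA", "spB"), ...) {
  cfg <- list(seed = seed, genome = genome, n_coding = n_coding,
              n_lncRNA = n_lncRNA, n_decoy = n_decoy, n_short = n_short,
              frac_maternal = frac_maternal, frac_embryonic = frac_embryonic,
              logfc_magnitude = logfc_magnitude,
              dispersion_true = dispersion_true,
              n_housekeeping_true = n_housekeeping_true,
              stage_effect_sd = stage_effect_sd,
              frac_lnc_violation = frac_lnc_violation,
              frac_lnc_genic = frac_lnc_genic, cage_frac = cage_frac,
              n_planted_syntenic = n_planted_syntenic,
              n_planted_conserved = n_planted_conserved,
              n_background_blocks = n_background_blocks,
              n_te_lnc_loci = n_te_lnc_loci,
              n_te_coding_loci = n_te_coding_loci,
              n_tss_ltr_lnc = n_tss_ltr_lnc,
              n_tss_ltr_coding = n_tss_ltr_coding,
              te_background_per_mb = te_background_per_mb,
              species = species,
              stages = c("egg", "epi30", "hpf24"),
              coding_exon_meanlog = log(180), coding_exon_sdlog = 0.6,
              coding_intron_meanlog = log(400), coding_intron_sdlog = 0.7,
              coding_exon_rate = 4,
              lnc_exon_meanlog = log(350), lnc_exon_sdlog = 0.6,
              lnc_intron_meanlog = log(450), lnc_intron_sdlog = 0.8,
              lnc_exon_rate = 1.2,
              coding_mean_log = log(150), coding_mean_sdlog = 1.0,
              lnc_mean_log = log(25), lnc_mean_sdlog = 1.0,
              depth_range = c(0.95, 1.05),
              intergap_meanlog = log(3000), intergap_sdlog = 0.6,
              flank_margin = c(5200, 9500),
              n_go_terms = 40, marker_go = "GO:1999999",
              co_expression_frac = 0.6,
              min_length = 200, cage_tpm_min = 0.5)
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(frac_maternal >= 0, frac_embryonic >= 0,
            frac_maternal + frac_embryonic <= 1, dispersion_true > 0,
            all(genome > 0), length(species) == 2)
  class(cfg) <- "sim_config"
  cfg
}

# random exon/intron structure for one transcript
.rand_struct <- function(cfg, biotype, n_exons = NULL, strand = NULL) {
  if (is.null(n_exons))
    n_exons <- 1 + stats::rpois(1, if (biotype == "coding")
      cfg$coding_exon_rate else cfg$lnc_exon_rate)
  ml <- if (biotype == "coding") cfg$coding_exon_meanlog else cfg$lnc_exon_meanlog
  sl <- if (biotype == "coding") cfg$coding_exon_sdlog else cfg$lnc_exon_sdlog
  iml <- if (biotype == "coding") cfg$coding_intron_meanlog else cfg$lnc_intron_meanlog
  isl <- if (biotype == "coding") cfg$coding_intron_sdlog else cfg$lnc_intron_sdlog
  ew <- pmax(40, round(stats::rlnorm(n_exons, ml, sl)))
  # generated lncRNAs respect the 200-nt assembly cutoff; sub-length
  # features are planted explicitly
  if (biotype != "coding" && sum(ew) <= 210) ew[1] <- ew[1] + 211 - sum(ew)
  iw <- if (n_exons > 1) pmax(60, round(stats::rlnorm(n_exons - 1, iml, isl)))
    else numeric(0)
  list(ew = ew, iw = iw,
       strand = if (is.null(strand)) sample(c("+", "-"), 1) else strand,
       span = sum(ew) + sum(iw))
}

# exon rows for a structure placed at pos
.struct_exons <- function(id, chrom, pos, st) {
  starts <- pos + cumsum(c(0, utils::head(st$ew, -1) + st$iw))
  data.frame(transcript_id = id, chrom = chrom, start = starts,
             end = starts + st$ew, strand = st$strand,
             stringsAsFactors = FALSE)
}

# secondary isoform: primary exons minus randomly dropped internal ones
.isoform_exons <- function(primary, id) {
  n <- nrow(primary)
  keep <- rep(TRUE, n)
  if (n > 2) keep[2:(n - 1)] <- stats::runif(n - 2) > 0.35
  e <- primary[keep, , drop = FALSE]
  e$transcript_id <- id
  e
}

# lay groups of features along the genome; returns exon/transcript tables.
# Each group: list(items = list(list(id, locus, struct, type, offset_mode)),
#               margin = logical) — see .build_groups below.
.layout_groups <- function(groups, genome, cfg) {
  chroms <- names(genome)
  ci <- 1
  cursor <- 3000
  pending <- 0
  placed <- list()
  gap_lo <- cfg$flank_margin[1]; gap_hi <- cfg$flank_margin[2]
  for (g in groups) {
    lead <- if (g$margin) stats::runif(1, gap_lo, gap_hi)
      else max(500, round(stats::rlnorm(1, cfg$intergap_meanlog,
                                        cfg$intergap_sdlog)))
    lead <- max(lead, pending)
    # relative offsets of the group's items
    offs <- numeric(length(g$items))
    cur <- 0
    for (k in seq_along(g$items)) {
      it <- g$items[[k]]
      if (!is.null(it$at)) {            # overlay: relative to first item
        offs[k] <- it$at
      } else {
        if (k > 1) cur <- cur + stats::runif(1, gap_lo, gap_hi)
        offs[k] <- cur
        cur <- cur + it$struct$span
      }
    }
    width <- max(offs + vapply(g$items, function(it) it$struct$span, 0))
    while (cursor + lead + width > genome[[chroms[ci]]] - 3000) {
      ci <- ci + 1
      if (ci > length(chroms))
        stop("genome too small to place the requested features; ",
             "increase chromosome lengths or reduce feature counts")
      cursor <- 3000
      pending <- 0
      lead <- max(lead, pending)
    }
    base <- cursor + lead
    for (k in seq_along(g$items)) {
      it <- g$items[[k]]
      it$chrom <- chroms[ci]
      it$pos <- base + offs[k]
      placed[[length(placed) + 1]] <- it
    }
    cursor <- base + width
    pending <- if (g$margin) gap_lo else 0
  }
  placed
}

# build the group list for one species
.build_groups <- function(cfg, sp, gene_structs, gene_ids, triples, overlays,
                          standalones) {
  used <- c(unlist(lapply(triples, function(t) t[c("u", "d")])),
            vapply(overlays, function(o) o$host, ""))
  free <- setdiff(gene_ids, used)
  groups <- list()
  for (t in triples) {
    groups[[length(groups) + 1]] <- list(margin = TRUE, items = list(
      list(id = t$u, locus = t$u, struct = gene_structs[[t$u]], type = "gene"),
      list(id = t$feature_id, locus = t$feature_locus,
           struct = t$struct, type = t$type),
      list(id = t$d, locus = t$d, struct = gene_structs[[t$d]], type = "gene")))
  }
  for (o in overlays) {
    host <- gene_structs[[o$host]]
    at <- switch(o$mode,
      center = max(0, floor((host$span - o$struct$span) / 2)),
      downstream = if (host$strand == "+") host$span + o$dist
        else -(o$dist + o$struct$span))
    items <- list(
      list(id = o$host, locus = o$host, struct = host, type = "gene"),
      list(id = o$feature_id, locus = o$feature_locus, struct = o$struct,
           type = o$type, at = at))
    # negative offsets (minus-strand downstream) shift the group
    mn <- min(0, at)
    if (mn < 0) for (k in seq_along(items))
      items[[k]]$at <- (if (is.null(items[[k]]$at)) 0 else items[[k]]$at) - mn
    groups[[length(groups) + 1]] <- list(margin = TRUE, items = items)
  }
  for (id in free)
    groups[[length(groups) + 1]] <- list(margin = FALSE, items = list(
      list(id = id, locus = id, struct = gene_structs[[id]], type = "gene")))
  for (s in standalones)
    groups[[length(groups) + 1]] <- list(margin = FALSE, items = list(
      list(id = s$feature_id, locus = s$feature_locus, struct = s$struct,
           type = s$type)))
  sample(groups)
}

# assemble transcript/exon tables from placed items for one species
.tables_from_placed <- function(placed, cfg, sp, hk_loci = character()) {
  tx <- list(); ex <- list()
  for (it in placed) {
    if (it$type == "gene") {
      lid <- it$id
      n_tx <- if (lid %in% hk_loci) sample(2:4, 1)
        else 1 + stats::rpois(1, 0.25)
      primary <- .struct_exons(paste0(lid, "_t1"), it$chrom, it$pos, it$struct)
      rows <- list(primary)
      if (n_tx > 1) for (j in 2:n_tx)
        rows[[j]] <- .isoform_exons(primary, paste0(lid, "_t", j))
      for (r in rows) {
        tx[[length(tx) + 1]] <- data.frame(
          transcript_id = r$transcript_id[1], locus_id = lid,
          chrom = it$chrom, strand = it$struct$strand, biotype = "coding",
          stringsAsFactors = FALSE)
        ex[[length(ex) + 1]] <- r
      }
    } else {
      tid <- paste0(it$id, "_t1")
      tx[[length(tx) + 1]] <- data.frame(
        transcript_id = tid, locus_id = it$locus, chrom = it$chrom,
        strand = it$struct$strand, biotype = "unclassified",
        stringsAsFactors = FALSE)
      ex[[length(ex) + 1]] <- .struct_exons(tid, it$chrom, it$pos, it$struct)
    }
  }
  transcript_set(do.call(rbind, tx), do.call(rbind, ex))
}

#' Generate the annotated genomes of both species with planted truth
#'
#' Lays out coding genes, lncRNAs (clean intergenic, positional-filter
#' violations, antisense genic), NCP decoys and sub-length transcripts on
#' the focal genome; lays out the second species with the planted
#' microsyntenic flank arrangement; draws the per-transcript annotation
#' evidence (homology flags, ORF length, NCP, SwissProt, GO terms); and
#' assigns expression labels (maternal / embryonic / stable, housekeeping).
#'
#' @param cfg a [simulation_config()]
#' @return list with `models` (focal `transcript_set`), `annotation`,
#'   `go_map`, `species_models` (named list of `transcript_set`s) and
#'   `truth` (planted ground-truth list)
#' @export
simulate_annotation <- function(cfg) {
  .with_seed(cfg$seed + 101, .simulate_annotation_impl(cfg))
}

.simulate_annotation_impl <- function(cfg) {
  spA <- cfg$species[1]; spB <- cfg$species[2]
  fam <- sprintf("fam%03d", seq_len(cfg$n_coding))
  gid <- function(sp, f) paste0(sp, "_", f)

  n_viol <- round(cfg$n_lncRNA * cfg$frac_lnc_violation)
  n_viol <- n_viol - n_viol %% 4
  n_genic <- round(cfg$n_lncRNA * cfg$frac_lnc_genic)
  n_clean <- cfg$n_lncRNA - n_viol - n_genic
  stopifnot(n_clean >= cfg$n_planted_syntenic + cfg$n_planted_conserved)

  lnc_ids_A <- sprintf("%s_lnc%03d", spA, seq_len(cfg$n_lncRNA))
  clean_A <- lnc_ids_A[seq_len(n_clean)]
  viol_A <- if (n_viol) lnc_ids_A[n_clean + seq_len(n_viol)] else character()
  genic_A <- if (n_genic) lnc_ids_A[n_clean + n_viol + seq_len(n_genic)]
    else character()
  synt_A <- clean_A[seq_len(cfg$n_planted_syntenic)]
  cons_A <- clean_A[cfg$n_planted_syntenic + seq_len(cfg$n_planted_conserved)]
  viol_modes <- rep(c("mono_overlap", "mono_downstream", "sense_overlap",
                      "sense_downstream"), length.out = n_viol)

  # reserved flank families for planted syntenic pairs
  synt_fams <- matrix(sample(fam, 2 * cfg$n_planted_syntenic), ncol = 2)

  build_species <- function(sp, lnc_clean_ids, synt_ids, viol_ids, viol_modes,
                            genic_ids, decoy_ids, short_ids) {
    structs <- lapply(fam, function(f) .rand_struct(cfg, "coding"))
    names(structs) <- vapply(fam, function(f) gid(sp, f), "")
    ids <- names(structs)
    triples <- list()
    # planted syntenic lincs sit between the reserved orthologous flanks
    for (k in seq_along(synt_ids)) {
      triples[[length(triples) + 1]] <- list(
        u = gid(sp, synt_fams[k, 1]), d = gid(sp, synt_fams[k, 2]),
        feature_id = synt_ids[k], feature_locus = synt_ids[k],
        struct = .rand_struct(cfg, "lnc"), type = "lnc")
    }
    # remaining clean lincs between random unused flanks
    other_clean <- setdiff(lnc_clean_ids, synt_ids)
    pool <- setdiff(ids, unlist(lapply(triples, function(t) c(t$u, t$d))))
    need <- 2 * length(other_clean)
    if (need > length(pool))
      stop("genome too small: not enough coding genes to flank all lincRNAs")
    flanks <- matrix(sample(pool, need), ncol = 2)
    for (k in seq_along(other_clean)) {
      triples[[length(triples) + 1]] <- list(
        u = flanks[k, 1], d = flanks[k, 2],
        feature_id = other_clean[k], feature_locus = other_clean[k],
        struct = .rand_struct(cfg, "lnc"), type = "lnc")
    }
    pool <- setdiff(pool, as.vector(flanks))
    # violation and antisense overlays need roomy hosts
    overlays <- list()
    overlay_ids <- c(viol_ids, genic_ids)
    overlay_modes <- c(viol_modes, rep("antisense_overlap", length(genic_ids)))
    if (length(overlay_ids)) {
      spans <- vapply(structs[pool], function(s) s$span, 0)
      hosts <- pool[order(-spans)][seq_along(overlay_ids)]
      pool <- setdiff(pool, hosts)
      for (k in seq_along(overlay_ids)) {
        m <- overlay_modes[k]
        host <- hosts[k]
        hs <- structs[[host]]
        if (m %in% c("mono_overlap", "mono_downstream")) {
          st <- .rand_struct(cfg, "lnc", n_exons = 1)
          st$ew <- min(max(st$ew, 250), max(250, hs$span - 200))
          st$span <- st$ew
        } else {
          st <- .rand_struct(cfg, "lnc", n_exons = 2)
          while (st$span > max(900, hs$span - 200))
            st <- .rand_struct(cfg, "lnc", n_exons = 2)
        }
        st$strand <- switch(m,
          mono_overlap = , mono_downstream = sample(c("+", "-"), 1),
          sense_overlap = , sense_downstream = hs$strand,
          antisense_overlap = if (hs$strand == "+") "-" else "+")
        overlays[[length(overlays) + 1]] <- list(
          host = host, feature_id = overlay_ids[k],
          feature_locus = overlay_ids[k], struct = st, type = "lnc",
          mode = if (grepl("downstream", m)) "downstream" else "center",
          dist = if (grepl("downstream", m)) round(stats::runif(1, 300, 3000))
            else 0)
      }
    }
    standalones <- c(
      lapply(decoy_ids, function(id) list(
        feature_id = id, feature_locus = id,
        struct = .rand_struct(cfg, "lnc",
                              n_exons = sample(1:2, 1)), type = "decoy")),
      lapply(short_ids, function(id) {
        st <- .rand_struct(cfg, "lnc", n_exons = 1)
        st$ew <- round(stats::runif(1, 120, 200))
        st$span <- st$ew
        list(feature_id = id, feature_locus = id, struct = st, type = "short")
      }))
    groups <- .build_groups(cfg, sp, structs, ids, triples, overlays,
                            standalones)
    placed <- .layout_groups(groups, cfg$genome, cfg)
    flank_map <- lapply(triples, function(t) c(t$u, t$d))
    names(flank_map) <- vapply(triples, function(t) t$feature_locus, "")
    list(placed = placed, flanks = flank_map)
  }

  decoys_A <- sprintf("%s_dec%03d", spA, seq_len(cfg$n_decoy))
  shorts_A <- sprintf("%s_sho%02d", spA, seq_len(cfg$n_short))
  built_A <- build_species(spA, clean_A, synt_A, viol_A, viol_modes,
                           genic_A, decoys_A, shorts_A)
  placed_A <- built_A$placed
  flank_map_A <- built_A$flanks

  # focal housekeeping loci
  hk_loci <- sample(vapply(fam, function(f) gid(spA, f), ""),
                    cfg$n_housekeeping_true)
  models_A <- .tables_from_placed(placed_A, cfg, spA, hk_loci)

  # species B: syntenic partners, conserved partners, background lincs
  synt_B <- sprintf("%s_lnc%03d", spB, seq_len(cfg$n_planted_syntenic))
  cons_B <- sprintf("%s_cns%03d", spB, seq_len(cfg$n_planted_conserved))
  n_bg_B <- max(0, cfg$n_lncRNA - n_viol - n_genic -
                  cfg$n_planted_syntenic - cfg$n_planted_conserved)
  bg_B <- sprintf("%s_bgl%03d", spB, seq_len(n_bg_B))
  placed_B <- build_species(spB, c(synt_B, cons_B, bg_B), synt_B,
                            character(), character(), character(),
                            character(), character())$placed
  models_B <- .tables_from_placed(placed_B, cfg, spB)

  # truth biotypes on the focal species
  tx_A <- models_A$transcripts
  # paste0 pads zero-length input to "", so guard explicitly
  lnc_tx <- function(ids) if (length(ids)) paste0(ids, "_t1") else character(0)
  truth_biotype <- stats::setNames(rep("coding", nrow(tx_A)),
                                   tx_A$transcript_id)
  truth_biotype[lnc_tx(clean_A)] <- "lincRNA"
  truth_biotype[lnc_tx(genic_A)] <- "lncRNA"
  truth_biotype[lnc_tx(viol_A)] <- "lncRNA_filtered"
  truth_biotype[lnc_tx(shorts_A)] <- "short"
  # decoys stay "coding" in truth

  # species B biotypes (used by conservation/synteny stages)
  tx_B <- models_B$transcripts
  is_lnc_B <- tx_B$transcript_id %in% lnc_tx(c(synt_B, cons_B, bg_B))
  models_B$transcripts$biotype <- ifelse(is_lnc_B, "lincRNA", "coding")
  models_A_labeled <- models_A
  bt_A <- truth_biotype[tx_A$transcript_id]
  models_A_labeled$transcripts$biotype <-
    ifelse(bt_A %in% c("lincRNA", "lncRNA", "lncRNA_filtered", "short"),
           "unclassified", "coding")

  # expression labels per locus: coding first, then lncRNAs, which inherit
  # the label of their upstream flanking gene with probability
  # co_expression_frac (planting the lncRNA/neighbour co-expression)
  loci_A <- unique(tx_A$locus_id)
  draw_lab <- function(n) sample(
    c("maternal", "embryonic", "stable"), n, replace = TRUE,
    prob = c(cfg$frac_maternal, cfg$frac_embryonic,
             1 - cfg$frac_maternal - cfg$frac_embryonic))
  coding_loci <- intersect(vapply(fam, function(f) gid(spA, f), ""), loci_A)
  non_hk_coding <- setdiff(coding_loci, hk_loci)
  expr_locus <- c(stats::setNames(draw_lab(length(non_hk_coding)),
                                  non_hk_coding),
                  stats::setNames(rep("stable", length(hk_loci)), hk_loci))
  other_loci <- setdiff(loci_A, coding_loci)
  lab_other <- draw_lab(length(other_loci))
  co_expressed <- character()
  for (k in seq_along(other_loci)) {
    fl <- flank_map_A[[other_loci[k]]]
    if (!is.null(fl) && stats::runif(1) < cfg$co_expression_frac) {
      lab_other[k] <- expr_locus[[fl[1]]]
      co_expressed[other_loci[k]] <- fl[1]
    }
  }
  expr_locus <- c(expr_locus, stats::setNames(lab_other, other_loci))
  expression <- stats::setNames(unname(expr_locus[tx_A$locus_id]),
                                tx_A$transcript_id)

  # annotation evidence
  n_tx <- nrow(tx_A)
  is_coding_tx <- truth_biotype == "coding" &
    !(tx_A$transcript_id %in% lnc_tx(decoys_A))
  is_decoy <- tx_A$transcript_id %in% lnc_tx(decoys_A)
  is_lncish <- !is_coding_tx & !is_decoy
  special <- lnc_tx(c(synt_A, cons_A))
  ncp <- numeric(n_tx)
  ncp[is_coding_tx] <- stats::rbeta(sum(is_coding_tx), 2, 8)
  ncp[is_decoy] <- stats::rbeta(sum(is_decoy), 4, 8)
  ncp[is_lncish] <- stats::rbeta(sum(is_lncish), 12, 3)
  sp_idx <- tx_A$transcript_id %in% special
  ncp[sp_idx] <- stats::qbeta(stats::runif(sum(sp_idx), 0.5, 1), 12, 3)
  orf <- integer(n_tx)
  orf[is_coding_tx] <- pmax(100, round(stats::rlnorm(sum(is_coding_tx),
                                                     log(300), 0.5)))
  orf[!is_coding_tx] <- round(stats::runif(sum(!is_coding_tx), 15, 99))
  prot <- is_coding_tx & stats::runif(n_tx) < 0.95
  dom <- is_coding_tx & stats::runif(n_tx) < 0.85
  # structural-RNA homology hits only on decoys, so planted lncRNA truth
  # stays consistent with the candidate rule
  ncrna <- is_decoy & stats::runif(n_tx) < 0.1
  hk_tx <- tx_A$transcript_id[tx_A$locus_id %in% hk_loci]
  swiss <- is_coding_tx & stats::runif(n_tx) < 0.8
  swiss[tx_A$transcript_id %in% hk_tx] <- TRUE

  # GO terms for coding loci; marker term near embryonic clean lincRNAs
  go_pool <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  emb_lincs <- intersect(lnc_tx(clean_A),
                         names(expression)[expression == "embryonic"])
  emb_spans <- tx_A[tx_A$transcript_id %in% emb_lincs, , drop = FALSE]
  coding_loci_tab <- locus_spans(subset_transcripts(
    models_A, tx_A$transcript_id[is_coding_tx | is_decoy]))
  near <- if (nrow(emb_spans))
    unique(window_pairs(emb_spans, coding_loci_tab, 10000,
                        s_id = "locus_id")$subject) else character()
  go_rows <- list()
  for (lid in unique(tx_A$locus_id[is_coding_tx])) {
    terms <- sample(go_pool, sample(1:4, 1))
    p_marker <- if (lid %in% near) 0.9 else 0.02
    if (stats::runif(1) < p_marker) terms <- c(terms, cfg$marker_go)
    for (tid in tx_A$transcript_id[tx_A$locus_id == lid])
      go_rows[[length(go_rows) + 1]] <-
        data.frame(id = tid, go_term = terms, stringsAsFactors = FALSE)
  }
  go_map <- do.call(rbind, go_rows)

  annotation <- data.frame(
    transcript_id = tx_A$transcript_id,
    has_protein_hit = prot, has_domain_hit = dom, has_ncrna_hit = ncrna,
    longest_orf_aa = orf, ncp = ncp, has_swissprot_hit = swiss,
    go_terms = vapply(tx_A$transcript_id, function(tid) {
      tm <- go_map$go_term[go_map$id == tid]
      paste(tm, collapse = ",")
    }, ""),
    stringsAsFactors = FALSE)

  truth <- list(
    biotype = truth_biotype,
    expression = expression,
    housekeeping_gene_ids = sort(hk_loci),
    housekeeping_transcript_ids = sort(hk_tx),
    violations = stats::setNames(viol_modes, lnc_tx(viol_A)),
    genic_antisense = lnc_tx(genic_A),
    decoys = lnc_tx(decoys_A),
    shorts = lnc_tx(shorts_A),
    syntenic_pairs = data.frame(
      linc_a = lnc_tx(synt_A), linc_b = lnc_tx(synt_B),
      flank_u = synt_fams[, 1], flank_d = synt_fams[, 2],
      stringsAsFactors = FALSE),
    conserved_pairs = data.frame(
      linc_a = lnc_tx(cons_A), linc_b = lnc_tx(cons_B),
      stringsAsFactors = FALSE),
    families = fam,
    co_expressed = co_expressed,
    marker_go = cfg$marker_go,
    embryonic_lincs = emb_lincs)

  list(models = models_A_labeled, annotation = annotation, go_map = go_map,
       species_models = stats::setNames(list(models_A_labeled, models_B),
                                        cfg$species),
       truth = truth)
}

#' Generate negative-binomial counts with planted stage structure
#'
#' Counts are NB with variance `mu + phi mu^2` at the configured true
#' dispersion. Maternal transcripts have `mu_egg = 2^logfc x mu_later`;
#' embryonic transcripts the reverse; housekeeping transcripts a constant
#' mean; other stable transcripts a small log-normal stage wobble. lncRNA
#' means are drawn from a lower log-normal than coding means. Library sizes
#' are the column sums.
#'
#' @param models focal `transcript_set` (from [simulate_annotation()])
#' @param truth planted-truth list
#' @param cfg a [simulation_config()]
#' @return a [count_matrix()] with attribute `"mu"` (the mean matrix)
#' @export
simulate_counts <- function(models, truth, cfg) {
  .with_seed(cfg$seed + 202, {
    tx <- models$transcripts
    n <- nrow(tx)
    is_lnc <- truth$biotype[tx$transcript_id] != "coding"
    base <- ifelse(is_lnc,
                   stats::rlnorm(n, cfg$lnc_mean_log, cfg$lnc_mean_sdlog),
                   stats::rlnorm(n, cfg$coding_mean_log, cfg$coding_mean_sdlog))
    stages <- cfg$stages
    mu <- matrix(base, n, length(stages),
                 dimnames = list(tx$transcript_id, stages))
    lab <- truth$expression[tx$transcript_id]
    hk <- tx$transcript_id %in% truth$housekeeping_transcript_ids
    fc <- 2^cfg$logfc_magnitude
    mu[lab == "maternal", 1] <- mu[lab == "maternal", 1] * fc
    mu[lab == "embryonic", -1] <- mu[lab == "embryonic", -1] * fc
    # per-locus stage effects: every non-housekeeping locus drifts between
    # stages; co-expressed lncRNA loci share their flanking gene's drift
    # (plus residual noise), planting the neighbour fold-change correlation
    loci <- unique(tx$locus_id)
    W <- matrix(stats::rnorm(length(loci) * length(stages), 0,
                             cfg$stage_effect_sd),
                nrow = length(loci), dimnames = list(loci, stages))
    ce <- truth$co_expressed
    if (length(ce)) {
      keep <- names(ce)[names(ce) %in% loci & ce %in% loci]
      W[keep, ] <- W[ce[keep], ] +
        matrix(stats::rnorm(length(keep) * length(stages), 0, 0.2),
               nrow = length(keep))
    }
    hk_loci <- unique(tx$locus_id[hk])
    W[hk_loci, ] <- 0
    mu <- mu * 2^W[tx$locus_id, , drop = FALSE]
    depth <- stats::runif(length(stages), cfg$depth_range[1],
                          cfg$depth_range[2])
    mu <- sweep(mu, 2, depth, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$dispersion_true),
                     nrow = n, dimnames = dimnames(mu))
    cm <- count_matrix(counts)
    attr(cm, "mu") <- mu
    cm
  })
}

#' Generate CAGE tags with configured promoter support
#'
#' A configured fraction of transcripts per biotype receives a supporting
#' tag (within the oriented -1000/+400 promoter window, tpm >= the cutoff);
#' half of the unsupported transcripts receive a decoy tag that fails
#' either the tpm cutoff or the window, exercising both failure modes.
#'
#' @param models focal `transcript_set`
#' @param truth planted-truth list
#' @param cfg a [simulation_config()]
#' @return list with `tags` (data.frame `chrom`, `pos`, `strand`, `tpm`)
#'   and `supported` (named logical truth per transcript)
#' @export
simulate_cage <- function(models, truth, cfg) {
  .with_seed(cfg$seed + 303, {
    tx <- models$transcripts
    tss <- tss_position(models)
    is_lnc <- truth$biotype[tx$transcript_id] %in%
      c("lncRNA", "lincRNA", "lncRNA_filtered")
    frac <- ifelse(is_lnc, cfg$cage_frac[["lncRNA"]],
                   cfg$cage_frac[["coding"]])
    supported <- stats::runif(nrow(tx)) < frac
    rows <- list()
    for (i in seq_len(nrow(tx))) {
      dirn <- if (tx$strand[i] == "+") 1 else -1
      if (supported[i]) {
        off <- round(stats::runif(1, -200, 100))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = tx$chrom[i], pos = tss[i] + dirn * off,
          strand = tx$strand[i],
          tpm = cfg$cage_tpm_min + stats::rexp(1, 0.5),
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.5) {
        if (stats::runif(1) < 0.5) {
          # in-window tag below the tpm cutoff
          off <- round(stats::runif(1, -200, 100))
          rows[[length(rows) + 1]] <- data.frame(
            chrom = tx$chrom[i], pos = tss[i] + dirn * off,
            strand = tx$strand[i],
            tpm = stats::runif(1, 0.01, cfg$cage_tpm_min - 0.05),
            stringsAsFactors = FALSE)
        } else {
          # strong tag outside the window (3' of the +400 bound)
          off <- round(stats::runif(1, 500, 900))
          rows[[length(rows) + 1]] <- data.frame(
            chrom = tx$chrom[i], pos = tss[i] + dirn * off,
            strand = tx$strand[i],
            tpm = cfg$cage_tpm_min + stats::rexp(1, 0.5),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(tags = do.call(rbind, rows),
         supported = stats::setNames(supported, tx$transcript_id))
  })
}

#' Generate repeat elements with planted exonic and TSS associations
#'
#' Background repeats (classes LINE, SINE, DNA, LTR with families including
#' ERVK) are placed uniformly but rejected from all exonic space, so the
#' planted exonic insertions are exactly the TE-bearing loci; TSS LTRs are
#' placed to contain the 5' base of designated transcripts.
#'
#' @param genome named chromosome lengths
#' @param models focal `transcript_set`
#' @param truth planted-truth list
#' @param cfg a [simulation_config()]
#' @return list with `repeats` (data.frame) and truth elements `te_loci`
#'   (per biotype) and `tss_te_transcripts`
#' @export
simulate_repeats <- function(genome, models, truth, cfg) {
  .with_seed(cfg$seed + 404, {
    classes <- c("LINE", "SINE", "DNA", "LTR")
    fams <- list(LINE = c("L1", "L2"), SINE = c("SINE2"),
                 DNA = c("hAT", "TcMar"), LTR = c("ERVK", "ERV1", "Gypsy"))
    tx <- models$transcripts
    bt <- truth$biotype[tx$transcript_id]
    lnc_tx_ids <- tx$transcript_id[bt %in% c("lncRNA", "lincRNA")]
    cod_tx_ids <- tx$transcript_id[bt == "coding" &
                                     !(tx$transcript_id %in% truth$decoys)]
    rows <- list()
    plant_exonic <- function(ids, n, lnc_bias) {
      loci <- unique(tx$locus_id[tx$transcript_id %in% ids])
      loci <- sample(loci, min(n, length(loci)))
      for (lid in loci) {
        tid <- tx$transcript_id[tx$locus_id == lid][1]
        e <- models$exons[models$exons$transcript_id == tid, , drop = FALSE]
        e <- e[which.max(e$end - e$start), ]
        w <- max(30, min(round(stats::runif(1, 60, 250)), e$end - e$start))
        s <- e$start + floor(stats::runif(1, 0, e$end - e$start - w + 1))
        cl <- if (lnc_bias && stats::runif(1) < 0.5) "LTR"
          else sample(classes, 1)
        rows[[length(rows) + 1]] <<- data.frame(
          chrom = e$chrom, start = s, end = s + w,
          repeat_id = sprintf("rep_ex_%s", lid), strand = ".",
          te_class = cl, te_family = sample(fams[[cl]], 1),
          stringsAsFactors = FALSE)
      }
      loci
    }
    te_lnc <- plant_exonic(lnc_tx_ids, cfg$n_te_lnc_loci, TRUE)
    te_cod <- plant_exonic(cod_tx_ids, cfg$n_te_coding_loci, FALSE)
    plant_tss <- function(ids, n) {
      ids <- sample(ids, min(n, length(ids)))
      tss <- tss_position(models)[ids]
      chroms <- stats::setNames(tx$chrom, tx$transcript_id)[ids]
      for (k in seq_along(ids)) {
        lo <- tss[k] - round(stats::runif(1, 10, 200))
        hi <- tss[k] + round(stats::runif(1, 10, 200))
        rows[[length(rows) + 1]] <<- data.frame(
          chrom = chroms[k], start = max(0, lo), end = hi + 1,
          repeat_id = sprintf("rep_tss_%s", ids[k]), strand = ".",
          te_class = "LTR", te_family = "ERVK", stringsAsFactors = FALSE)
      }
      ids
    }
    tss_lnc <- plant_tss(setdiff(lnc_tx_ids, paste0(c(te_lnc), "_t1")),
                         cfg$n_tss_ltr_lnc)
    tss_cod <- plant_tss(cod_tx_ids, cfg$n_tss_ltr_coding)
    # background repeats avoiding all exonic space
    exon_space <- merge_intervals(models$exons)
    n_bg <- round(sum(genome) / 1e6 * cfg$te_background_per_mb)
    chroms <- names(genome)
    made <- 0; tries <- 0
    while (made < n_bg && tries < n_bg * 50) {
      tries <- tries + 1
      chrom <- sample(chroms, 1, prob = genome)
      w <- max(50, round(stats::rlnorm(1, log(300), 0.5)))
      s <- floor(stats::runif(1, 0, genome[[chrom]] - w))
      es <- exon_space[exon_space$chrom == chrom, , drop = FALSE]
      if (any(es$start < s + w & es$end > s)) next
      made <- made + 1
      cl <- sample(classes, 1, prob = c(0.3, 0.25, 0.3, 0.15))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = s, end = s + w,
        repeat_id = sprintf("rep_bg_%05d", made), strand = ".",
        te_class = cl, te_family = sample(fams[[cl]], 1),
        stringsAsFactors = FALSE)
    }
    locus_of <- stats::setNames(tx$locus_id, tx$transcript_id)
    list(repeats = do.call(rbind, rows),
         # TSS repeats overlap the first exon, so their loci are TE-bearing too
         te_loci = list(
           lncRNA = sort(unique(c(te_lnc, unname(locus_of[tss_lnc])))),
           coding = sort(unique(c(te_cod, unname(locus_of[tss_cod]))))),
         tss_te_transcripts = list(lncRNA = sort(unname(tss_lnc)),
                                   coding = sort(unname(tss_cod))))
  })
}

#' Generate multi-species alignment blocks
#'
#' Planted conserved lncRNA pairs receive 1-3 blocks whose per-species
#' elements are sub-intervals of their exons in each species; background
#' blocks are placed in intergenic space (avoiding every exon in both
#' species) with one element per species. Every block carries one
#' similarity score in (0, 1].
#'
#' @param species_models named list of `transcript_set`s
#' @param truth planted-truth list (uses `conserved_pairs`)
#' @param cfg a [simulation_config()]
#' @return data.frame of block elements (`block_id`, `species`, `chrom`,
#'   `start`, `end`, `score`)
#' @export
simulate_alignment_blocks <- function(species_models, truth, cfg) {
  .with_seed(cfg$seed + 505, {
    spA <- cfg$species[1]; spB <- cfg$species[2]
    rows <- list()
    sub_exon <- function(models, tid) {
      e <- models$exons[models$exons$transcript_id == tid, , drop = FALSE]
      e <- e[sample(nrow(e), 1), ]
      w <- max(25, min(round(stats::runif(1, 30, 200)), e$end - e$start))
      s <- e$start + floor(stats::runif(1, 0, e$end - e$start - w + 1))
      list(chrom = e$chrom, start = s, end = s + w)
    }
    bid <- 0
    cp <- truth$conserved_pairs
    for (k in seq_len(nrow(cp))) {
      for (j in seq_len(sample(1:3, 1))) {
        bid <- bid + 1
        sc <- stats::runif(1, 0.5, 1)
        ea <- sub_exon(species_models[[spA]], cp$linc_a[k])
        eb <- sub_exon(species_models[[spB]], cp$linc_b[k])
        rows[[length(rows) + 1]] <- data.frame(
          block_id = sprintf("blk%05d", bid),
          species = c(spA, spB),
          chrom = c(ea$chrom, eb$chrom),
          start = c(ea$start, eb$start), end = c(ea$end, eb$end),
          score = sc, stringsAsFactors = FALSE)
      }
    }
    spaces <- lapply(species_models, function(m) merge_intervals(m$exons))
    for (j in seq_len(cfg$n_background_blocks)) {
      bid <- bid + 1
      sc <- stats::runif(1, 0.05, 0.6)
      el <- lapply(cfg$species, function(sp) {
        repeat {
          chrom <- sample(names(cfg$genome), 1, prob = cfg$genome)
          w <- max(30, round(stats::rlnorm(1, log(120), 0.5)))
          s <- floor(stats::runif(1, 0, cfg$genome[[chrom]] - w))
          es <- spaces[[sp]]
          es <- es[es$chrom == chrom, , drop = FALSE]
          if (!any(es$start < s + w & es$end > s))
            return(list(chrom = chrom, start = s, end = s + w))
        }
      })
      rows[[length(rows) + 1]] <- data.frame(
        block_id = sprintf("blk%05d", bid), species = cfg$species,
        chrom = vapply(el, `[[`, "", "chrom"),
        start = vapply(el, `[[`, 0, "start"),
        end = vapply(el, `[[`, 0, "end"),
        score = sc, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Orthology table between the two simulated species
#'
#' One row per shared gene family; symmetric by construction.
#' @param truth planted-truth list
#' @param cfg a [simulation_config()]
#' @return data.frame with `gene_a`, `gene_b`
#' @export
simulate_orthology <- function(truth, cfg) {
  data.frame(gene_a = paste0(cfg$species[1], "_", truth$families),
             gene_b = paste0(cfg$species[2], "_", truth$families),
             stringsAsFactors = FALSE)
}

#' Generate the complete synthetic dataset
#'
#' Runs every generator with sub-seeds derived from the master seed and
#' assembles the full input bundle for the pipeline, with all planted truth
#' recorded.
#'
#' @param cfg a [simulation_config()]
#' @return list of class `lncdev_dataset`: `config`, `genome`, `models`,
#'   `annotation`, `go_map`, `counts`, `cage`, `repeats`, `blocks`,
#'   `orthology`, `species_models`, `truth`
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  ann <- simulate_annotation(cfg)
  counts <- simulate_counts(ann$models, ann$truth, cfg)
  cage <- simulate_cage(ann$models, ann$truth, cfg)
  reps <- simulate_repeats(cfg$genome, ann$models, ann$truth, cfg)
  blocks <- simulate_alignment_blocks(ann$species_models, ann$truth, cfg)
  orth <- simulate_orthology(ann$truth, cfg)
  truth <- ann$truth
  truth$cage_supported <- cage$supported
  truth$te_loci <- reps$te_loci
  truth$tss_te_transcripts <- reps$tss_te_transcripts
  structure(list(config = cfg, genome = cfg$genome, models = ann$models,
                 annotation = ann$annotation, go_map = ann$go_map,
                 counts = counts, cage = cage$tags, repeats = reps$repeats,
                 blocks = blocks, orthology = orth,
                 species_models = ann$species_models, truth = truth),
            class = "lncdev_dataset")
}

#' Serialize / restore planted truth
#'
#' @param truth planted-truth list
#' @param path JSON path
#' @return `path` invisibly, or the restored truth list
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  # named atomic vectors must become JSON objects, not arrays
  for (f in names(tr))
    if (is.atomic(tr[[f]]) && !is.null(names(tr[[f]])))
      tr[[f]] <- as.list(tr[[f]])
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("biotype", "expression", "violations", "cage_supported"))
    if (!is.null(tr[[f]])) tr[[f]] <- unlist(tr[[f]])
  tr
}
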