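#' Run the full downstream pipeline on a dataset
#'
#' Orchestrates the stages in order — lncRNA classification, replicate-free
#' differential expression with housekeeping-inferred dispersion and
#' maternal/embryonic calling, conservation calling from alignment blocks,
#' microsynteny with the randomisation null, transposable-element
#' association, and GO enrichment — and returns a manifest of category
#' counts plus every stage's tables. Deterministic given `seed` (the single
#' seed fans out to per-stage seeds by fixed offsets). With `outdir` set,
#' stage outputs are written as TSV/BED/GTF plus a JSON manifest.
#'
#' @param dataset a bundle as produced by [simulate_dataset()] (or an
#'   equivalent list built from files: `models`, `annotation`, `counts`,
#'   `cage`, `repeats`, `blocks`, `orthology`, `species_models`, `genome`)
#' @param seed integer seed for the randomisation stages
#' @param outdir optional output directory
#' @param synteny_reps randomisation replicates for the microsynteny null
#'   (default 100; 0 skips the significance test but still emits calls)
#' @param n_housekeeping,fdr_max,min_abs_logfc,min_cpm,window key thresholds
#'   (defaults 100 genes, 0.01, 2, 0.5 CPM, 10 kb)
#' @return list with `manifest` (named list of summary counts and
#'   statistics) and `stages` (per-stage result objects)
#' @export
run_pipeline <- function(dataset, seed = 1, outdir = NULL, synteny_reps = 100,
                         n_housekeeping = 100, fdr_max = 0.01,
                         min_abs_logfc = 2, min_cpm = 0.5, window = 10000) {
  spA <- names(dataset$species_models)[1]
  spB <- names(dataset$species_models)[2]

  ## 1. classification
  cls <- classify_transcripts(dataset$models, dataset$annotation,
                              cage = dataset$cage)
  classified <- dataset$models
  bt <- stats::setNames(cls$results$stage_reached, cls$results$transcript_id)
  classified$transcripts$biotype <- ifelse(
    bt[classified$transcripts$transcript_id] == "lincRNA", "lincRNA",
    ifelse(bt[classified$transcripts$transcript_id] == "lncRNA", "lncRNA",
           "coding"))

  ## 2. differential expression
  loci <- stats::setNames(dataset$models$transcripts$locus_id,
                          dataset$models$transcripts$transcript_id)
  hk <- select_housekeeping(dataset$counts, dataset$annotation, loci,
                            n_genes = n_housekeeping)
  hk_cm <- count_matrix(
    dataset$counts$counts[hk$housekeeping_transcript_ids, , drop = FALSE],
    dataset$counts$library_sizes)
  phi <- estimate_dispersion(hk_cm)
  de <- run_de(dataset$counts, phi, min_cpm = min_cpm, fdr_max = fdr_max,
               min_abs_logfc = min_abs_logfc)
  stage_sets <- classify_stage_specific(de)
  corr <- tryCatch(
    neighbor_fc_correlation(de, cls$lncRNAs, cls$coding, window = window),
    error = function(e) list(rho = NA_real_, p = NA_real_, n_pairs = 0))

  ## 3. conservation
  lnc_by_species <- list(cls$lncRNAs,
                         subset_transcripts(
                           dataset$species_models[[spB]],
                           dataset$species_models[[spB]]$transcripts$transcript_id[
                             dataset$species_models[[spB]]$transcripts$biotype %in%
                               c("lncRNA", "lincRNA")]))
  names(lnc_by_species) <- c(spA, spB)
  cons <- call_conserved_lncRNAs(lnc_by_species, dataset$blocks)
  cons_scores <- score_conservation(
    cls$lncRNAs, dataset$blocks[dataset$blocks$species == spA, , drop = FALSE])

  ## 4. microsynteny
  coding_B <- subset_transcripts(
    dataset$species_models[[spB]],
    dataset$species_models[[spB]]$transcripts$transcript_id[
      dataset$species_models[[spB]]$transcripts$biotype == "coding"])
  lincs_per_species <- stats::setNames(
    list(cls$lincRNAs, lnc_by_species[[spB]]), c(spA, spB))
  coding_per_species <- stats::setNames(list(cls$coding, coding_B), c(spA, spB))
  orthology_maps <- stats::setNames(list(dataset$orthology),
                                    paste0(spA, "|", spB))
  genomes <- stats::setNames(list(dataset$genome, dataset$genome), c(spA, spB))
  if (synteny_reps > 0) {
    syn <- synteny_randomization(lincs_per_species, coding_per_species,
                                 orthology_maps, genomes,
                                 n_reps = synteny_reps, seed = seed + 1000)
  } else {
    obs <- .synteny_percent(lincs_per_species, coding_per_species,
                            orthology_maps, c(spA, spB))
    syn <- list(observed = obs$percent, null_mean = NA_real_,
                null_sd = NA_real_, z = NA_real_, p = NA_real_,
                calls = obs$calls, multi_species = obs$multi_species)
  }

  ## 5. transposable elements
  te_loci <- exonic_te_loci(classified, dataset$repeats)
  te_cov <- te_coverage(cls$lncRNAs, dataset$repeats, by = "te_class")
  te_enr <- te_enrichment(cls$lncRNAs, dataset$repeats, dataset$genome,
                          by = "te_class")
  tss_te <- tss_associated_te(classified, dataset$repeats)

  ## 6. GO enrichment
  tested_ids <- unique(de$transcript_id)
  coding_tested <- intersect(tested_ids, cls$coding$transcripts$transcript_id)
  go_mat <- tryCatch(
    fisher_go_enrichment(intersect(stage_sets$maternal, coding_tested),
                         coding_tested, dataset$go_map),
    error = function(e) NULL)
  go_emb <- tryCatch(
    fisher_go_enrichment(intersect(stage_sets$embryonic, coding_tested),
                         coding_tested, dataset$go_map),
    error = function(e) NULL)
  emb_linc_ids <- intersect(stage_sets$embryonic,
                            cls$lincRNAs$transcripts$transcript_id)
  go_prox <- if (length(emb_linc_ids))
    proximal_go_enrichment(subset_transcripts(cls$lincRNAs, emb_linc_ids),
                           cls$lincRNAs, cls$coding, dataset$go_map,
                           window = window)
    else NULL

  ## manifest: differential / maternal / embryonic x coding / lnc / linc
  biotype_of <- stats::setNames(classified$transcripts$biotype,
                                classified$transcripts$transcript_id)
  locus_of <- loci
  count_cat <- function(ids, class_) {
    ids <- ids[!is.na(biotype_of[ids])]
    sel <- if (class_ == "coding") ids[biotype_of[ids] == "coding"]
      else if (class_ == "lncRNA")
        ids[biotype_of[ids] %in% c("lncRNA", "lincRNA")]
      else ids[biotype_of[ids] == "lincRNA"]
    c(transcripts = length(sel),
      loci = length(unique(unname(locus_of[sel]))))
  }
  diff_ids <- unique(de$transcript_id[de$call != "ns"])
  cats <- list(differential = diff_ids, maternal = stage_sets$maternal,
               embryonic = stage_sets$embryonic)
  table1 <- lapply(cats, function(ids)
    lapply(stats::setNames(c("coding", "lncRNA", "lincRNA"),
                           c("coding", "lncRNA", "lincRNA")),
           function(cl) as.list(count_cat(ids, cl))))

  manifest <- list(
    n_transcripts = nrow(dataset$models$transcripts),
    n_loci = length(unique(dataset$models$transcripts$locus_id)),
    n_lncRNA_transcripts = nrow(cls$lncRNAs$transcripts),
    n_lncRNA_loci = length(unique(cls$lncRNAs$transcripts$locus_id)),
    n_lincRNA_transcripts = nrow(cls$lincRNAs$transcripts),
    ncp_cutoff = cls$ncp_cutoff,
    dispersion = as.numeric(phi),
    n_housekeeping_transcripts = length(hk$housekeeping_transcript_ids),
    expression_classes = table1,
    neighbor_rho = corr$rho,
    neighbor_rho_p = corr$p,
    n_conserved_lncRNAs = length(cons$conserved[[spA]]),
    synteny_observed_pct = syn$observed,
    synteny_z = syn$z,
    synteny_p = syn$p,
    te_pct_lnc_loci = {
      r <- te_loci[te_loci$biotype %in% c("lncRNA", "lincRNA"), , drop = FALSE]
      if (nrow(r)) 100 * sum(r$n_te_loci) / sum(r$n_loci) else 0
    },
    n_tss_te = sum(tss_te$tss_associated),
    n_go_enriched_embryonic = if (is.null(go_emb)) 0 else
      sum(go_emb$significant),
    n_go_enriched_proximal = if (is.null(go_prox)) 0 else
      sum(go_prox$significant),
    seed = seed)

  stages <- list(classification = cls, housekeeping = hk, dispersion = phi,
                 de = de, stage_sets = stage_sets, correlation = corr,
                 conservation = cons, conservation_scores = cons_scores,
                 synteny = syn, te_loci = te_loci, te_coverage = te_cov,
                 te_enrichment = te_enr, tss_te = tss_te,
                 go_maternal = go_mat, go_embryonic = go_emb,
                 go_proximal = go_prox, classified_models = classified)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cls$results, file.path(outdir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed12(cls$lncRNAs, file.path(outdir, "lncRNAs.bed"))
    if (nrow(cls$lincRNAs$transcripts))
      write_bed12(cls$lincRNAs, file.path(outdir, "lincRNAs.bed"))
    utils::write.table(de, file.path(outdir, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(te_loci, file.path(outdir, "te_loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(manifest = manifest, stages = stages)
}
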