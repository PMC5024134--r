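#' Minimum-length filter for assembled transcripts
#'
#' Retains transcripts whose mature length (summed exon widths) exceeds
#' `min_length` nt. The comparison is strict by default ("longer than"),
#' configurable via `strict`.
#'
#' @param ts a `transcript_set`
#' @param min_length length threshold in nt (default 200)
#' @param strict if `TRUE` keep length > `min_length`; else >= `min_length`
#' @return a filtered `transcript_set`
#' @export
filter_min_length <- function(ts, min_length = 200, strict = TRUE) {
  len <- transcript_lengths(ts)
  keep <- if (strict) len > min_length else len >= min_length
  if (!any(keep)) {
    empty <- ts
    empty$transcripts <- ts$transcripts[0, , drop = FALSE]
    empty$exons <- ts$exons[0, , drop = FALSE]
    return(empty)
  }
  subset_transcripts(ts, names(len)[keep])
}

#' Call candidate lncRNAs from annotation evidence
#'
#' A transcript is a candidate lncRNA when it shows no homology to known
#' proteins, protein domains or structural/small RNAs and its longest ORF is
#' shorter than `max_orf_aa` amino acids.
#'
#' @param records annotation data.frame (see [read_annotation_table()])
#' @param max_orf_aa ORF threshold in amino acids; candidates have
#'   `longest_orf_aa < max_orf_aa` (default 100, strict)
#' @return character vector of candidate transcript ids
#' @export
call_candidates <- function(records, max_orf_aa = 100) {
  if (anyDuplicated(records$transcript_id))
    stop("duplicate transcript_id in annotation records")
  keep <- !records$has_protein_hit & !records$has_domain_hit &
    !records$has_ncrna_hit & records$longest_orf_aa < max_orf_aa
  records$transcript_id[keep]
}

#' Non-coding-potential cutoff from candidate lncRNAs
#'
#' The data-driven NCP cutoff: the arithmetic mean of the candidates' NCP
#' scores. Potential lncRNAs are candidates whose NCP is strictly greater
#' than this mean.
#'
#' @param records annotation rows of the candidate transcripts
#' @return the mean NCP of the candidates
#' @export
ncp_cutoff <- function(records) {
  if (nrow(records) == 0) stop("no candidate lncRNAs: cannot compute NCP cutoff")
  mean(records$ncp)
}

# downstream windows of coding genes: the `bp` interval 3' of each gene in
# its own orientation
.downstream_windows <- function(coding_spans, bp) {
  plus <- coding_spans$strand != "-"
  data.frame(chrom = coding_spans$chrom,
             start = pmax(0, ifelse(plus, coding_spans$end,
                                    coding_spans$start - bp)),
             end = ifelse(plus, coding_spans$end + bp, coding_spans$start),
             strand = coding_spans$strand,
             stringsAsFactors = FALSE)
}

#' Positional filter against coding genes
#'
#' Removes potential lncRNAs that are plausible read-through or alternative
#' polyadenylation products of coding genes: (a) mono-exonic transcripts
#' overlapping a coding gene or lying within `downstream_bp` of a coding
#' gene's 3' end, irrespective of strand; (b) multi-exonic transcripts doing
#' either on the same strand as the coding gene. "Downstream" is measured in
#' the coding gene's orientation.
#'
#' @param potentials `transcript_set` of potential lncRNAs
#' @param coding `transcript_set` of coding gene models (locus spans used)
#' @param downstream_bp 3'-flank width in bp (default 5000)
#' @return list with `kept` (a `transcript_set`) and `removed` (data.frame
#'   with `transcript_id` and `reason`)
#' @export
positional_filter <- function(potentials, coding, downstream_bp = 5000) {
  tx <- potentials$transcripts
  removed <- data.frame(transcript_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (nrow(coding$transcripts) == 0 || nrow(tx) == 0)
    return(list(kept = potentials, removed = removed))

  spans <- locus_spans(coding)
  down <- .downstream_windows(spans, downstream_bp)
  nex <- n_exons(potentials)

  ov <- .overlap_hits(tx, spans)
  dv <- .overlap_hits(tx, down)
  ov$same <- tx$strand[ov$q] == spans$strand[ov$s]
  dv$same <- tx$strand[dv$q] == down$strand[dv$s]

  mono <- nex[tx$transcript_id] == 1
  drop_reason <- rep(NA_character_, nrow(tx))
  # mono-exonic: any-strand overlap or downstream proximity
  hit_ov_any <- unique(ov$q)
  hit_dv_any <- unique(dv$q)
  drop_reason[intersect(which(mono), hit_ov_any)] <- "mono_exonic_overlaps_coding"
  nafill <- function(i, val) ifelse(is.na(drop_reason[i]), val, drop_reason[i])
  i <- intersect(which(mono), hit_dv_any)
  drop_reason[i] <- nafill(i, "mono_exonic_downstream_of_coding")
  # multi-exonic: same-strand only
  hit_ov_same <- unique(ov$q[ov$same])
  hit_dv_same <- unique(dv$q[dv$same])
  i <- intersect(which(!mono), hit_ov_same)
  drop_reason[i] <- nafill(i, "same_strand_overlaps_coding")
  i <- intersect(which(!mono), hit_dv_same)
  drop_reason[i] <- nafill(i, "same_strand_downstream_of_coding")

  drop <- !is.na(drop_reason)
  removed <- data.frame(transcript_id = tx$transcript_id[drop],
                        reason = drop_reason[drop], stringsAsFactors = FALSE)
  kept <- if (all(drop)) {
    empty <- potentials
    empty$transcripts <- tx[0, , drop = FALSE]
    empty$exons <- potentials$exons[0, , drop = FALSE]
    empty
  } else subset_transcripts(potentials, tx$transcript_id[!drop])
  list(kept = kept, removed = removed)
}

#' Call long intergenic ncRNAs
#'
#' lincRNAs are lncRNAs whose span has zero overlap (strand-agnostic) with
#' any coding locus span (exons and introns of the coding locus).
#'
#' @param lncrnas `transcript_set` of final lncRNAs
#' @param coding `transcript_set` of coding models
#' @return character vector of lincRNA transcript ids
#' @export
call_lincRNAs <- function(lncrnas, coding) {
  tx <- lncrnas$transcripts
  if (nrow(tx) == 0) return(character())
  if (nrow(coding$transcripts) == 0) return(tx$transcript_id)
  spans <- locus_spans(coding)
  ov <- .overlap_hits(tx, spans)
  setdiff(tx$transcript_id, tx$transcript_id[unique(ov$q)])
}

#' CAGE support of transcription start sites
#'
#' A transcript is CAGE-supported when at least one tag with
#' `tpm >= min_tpm` falls in the strand-oriented promoter window
#' `[TSS - upstream, TSS + downstream]` around its 5' start (positions
#' inclusive; upstream means 5' of the TSS in transcript orientation). Tags
#' on the opposite strand are ignored; unstranded tags (`.`) match either.
#'
#' @param ts a `transcript_set`
#' @param tags CAGE tag data.frame (`chrom`, `pos`, `strand`, `tpm`)
#' @param upstream,downstream window half-widths in bp (defaults 1000/400)
#' @param min_tpm minimum tag expression (default 0.5, inclusive)
#' @return named logical vector per transcript
#' @export
cage_support <- function(ts, tags, upstream = 1000, downstream = 400,
                         min_tpm = 0.5) {
  tx <- ts$transcripts
  tss <- tss_position(ts)
  ok <- tags$tpm >= min_tpm
  tags <- tags[ok, , drop = FALSE]
  out <- logical(nrow(tx))
  names(out) <- tx$transcript_id
  if (nrow(tags) == 0) return(out)
  for (i in seq_len(nrow(tx))) {
    lo <- if (tx$strand[i] == "+") tss[i] - upstream else tss[i] - downstream
    hi <- if (tx$strand[i] == "+") tss[i] + downstream else tss[i] + upstream
    hit <- tags$chrom == tx$chrom[i] & tags$pos >= lo & tags$pos <= hi &
      (tags$strand == "." | tags$strand == tx$strand[i])
    out[i] <- any(hit)
  }
  out
}

#' Map assembled loci to reference gene models and ESTs
#'
#' A locus is `common` when any of its transcripts overlaps a reference gene
#' exonically on the same strand; `est_supported` when it is not common but
#' overlaps an EST interval (strand-agnostic); otherwise `novel`. For common
#' loci the span of the assembled locus is compared, strand-aware, to the
#' span of the best-matching reference locus (largest exonic overlap) and an
#' extension category is reported.
#'
#' @param assembled,reference `transcript_set` objects
#' @param ests data.frame of EST intervals (`chrom`, `start`, `end`), may be
#'   empty
#' @return data.frame per assembled locus: `locus_id`, `label`,
#'   `ref_locus`, `extension` (one of `both_ends`, `5p_only`, `3p_only`,
#'   `none`; `NA` for non-common loci)
#' @export
map_to_reference <- function(assembled, reference,
                             ests = genome_intervals(character(), numeric(),
                                                     numeric())[0, ]) {
  a_ex <- assembled$exons
  r_ex <- reference$exons
  a_loc <- stats::setNames(assembled$transcripts$locus_id,
                           assembled$transcripts$transcript_id)
  r_loc <- stats::setNames(reference$transcripts$locus_id,
                           reference$transcripts$transcript_id)
  hits <- .overlap_hits(a_ex, r_ex, stranded = TRUE)
  if (nrow(hits)) {
    hits$a_locus <- unname(a_loc[a_ex$transcript_id[hits$q]])
    hits$r_locus <- unname(r_loc[r_ex$transcript_id[hits$s]])
    hits$ovl <- overlap_length(a_ex[hits$q, ], r_ex[hits$s, ])
  }
  est_hits <- if (nrow(ests)) .overlap_hits(a_ex, ests) else
    data.frame(q = integer(), s = integer())
  est_loci <- unique(unname(a_loc[a_ex$transcript_id[est_hits$q]]))

  a_spans <- locus_spans(assembled)
  r_spans <- locus_spans(reference)
  out <- data.frame(locus_id = a_spans$locus_id, label = "novel",
                    ref_locus = NA_character_, extension = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    lid <- out$locus_id[i]
    h <- if (nrow(hits)) hits[hits$a_locus == lid, , drop = FALSE] else hits
    if (nrow(h)) {
      out$label[i] <- "common"
      ref <- names(which.max(tapply(h$ovl, h$r_locus, sum)))
      out$ref_locus[i] <- ref
      rs <- r_spans[r_spans$locus_id == ref, ]
      as_ <- a_spans[a_spans$locus_id == lid, ]
      left <- as_$start < rs$start
      right <- as_$end > rs$end
      minus <- rs$strand == "-"
      e5 <- if (minus) right else left
      e3 <- if (minus) left else right
      out$extension[i] <- if (e5 && e3) "both_ends" else if (e5) "5p_only"
        else if (e3) "3p_only" else "none"
    } else if (lid %in% est_loci) {
      out$label[i] <- "est_supported"
    }
  }
  out
}

#' Transcript anatomy statistics per biotype
#'
#' Exon/intron length distributions, exon counts, mono-exonic fraction and
#' the transcribed genomic fraction (merged exonic bp over genome bp) for
#' each biotype present in the set.
#'
#' @param ts a `transcript_set` with biotypes assigned
#' @param genome named numeric vector of chromosome lengths
#' @return data.frame with one row per biotype
#' @export
anatomy_stats <- function(ts, genome) {
  genome_bp <- sum(genome)
  introns <- intron_intervals(ts)
  bt_of <- stats::setNames(ts$transcripts$biotype, ts$transcripts$transcript_id)
  res <- lapply(sort(unique(ts$transcripts$biotype)), function(bt) {
    ids <- ts$transcripts$transcript_id[ts$transcripts$biotype == bt]
    ex <- ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE]
    int <- introns[bt_of[introns$transcript_id] == bt, , drop = FALSE]
    nex <- table(ex$transcript_id)
    data.frame(
      biotype = bt,
      n_transcripts = length(ids),
      n_loci = length(unique(ts$transcripts$locus_id[
        ts$transcripts$transcript_id %in% ids])),
      mean_exon_length = mean(ex$end - ex$start),
      median_exon_length = stats::median(ex$end - ex$start),
      mean_intron_length = if (nrow(int)) mean(int$end - int$start) else NA_real_,
      median_intron_length = if (nrow(int)) stats::median(int$end - int$start)
        else NA_real_,
      mean_exon_count = mean(as.integer(nex)),
      mono_exonic_fraction = mean(as.integer(nex) == 1),
      transcribed_fraction = covered_bases(ex) / genome_bp,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the full lncRNA classification cascade
#'
#' Applies, in order: the minimum mature-length filter; the evidence-based
#' candidate call (no homology, short ORF); the data-driven NCP cutoff
#' (strictly greater than the candidate mean); the positional filter against
#' coding genes; and the intergenic (lincRNA) call. CAGE support is recorded
#' for every retained transcript. Transcripts failing the candidate or NCP
#' steps are classified coding.
#'
#' @param ts assembled `transcript_set`
#' @param annotation annotation data.frame (one row per transcript)
#' @param cage optional CAGE tag data.frame
#' @param extra_coding optional `transcript_set` of reference coding models
#'   to include in the positional filter
#' @param min_length,max_orf_aa,downstream_bp,cage_upstream,cage_downstream,min_tpm
#'   cascade thresholds (defaults 200 nt, 100 aa, 5000 bp, 1000/400 bp,
#'   0.5 tpm)
#' @return list with `results` (one row per input transcript: `stage_reached`,
#'   `filter_reasons`, `cage_supported`), `lncRNAs` and `lincRNAs`
#'   (`transcript_set`s), `coding` (`transcript_set` used as the coding
#'   universe) and `ncp_cutoff`
#' @export
classify_transcripts <- function(ts, annotation, cage = NULL,
                                 extra_coding = NULL, min_length = 200,
                                 max_orf_aa = 100, downstream_bp = 5000,
                                 cage_upstream = 1000, cage_downstream = 400,
                                 min_tpm = 0.5) {
  all_ids <- ts$transcripts$transcript_id
  res <- data.frame(transcript_id = all_ids,
                    stage_reached = "discarded_short",
                    filter_reasons = "", cage_supported = NA,
                    stringsAsFactors = FALSE)
  rownames(res) <- all_ids

  retained <- filter_min_length(ts, min_length)
  short_ids <- setdiff(all_ids, retained$transcripts$transcript_id)
  res[short_ids, "filter_reasons"] <- sprintf("length<=%d", min_length)

  ann <- annotation[match(retained$transcripts$transcript_id,
                          annotation$transcript_id), , drop = FALSE]
  if (anyNA(ann$transcript_id))
    stop("annotation records missing for some retained transcripts")

  cand_ids <- call_candidates(ann, max_orf_aa)
  non_cand <- setdiff(retained$transcripts$transcript_id, cand_ids)
  reasons <- vapply(non_cand, function(id) {
    r <- ann[ann$transcript_id == id, ]
    parts <- c(if (r$has_protein_hit) "protein_hit",
               if (r$has_domain_hit) "domain_hit",
               if (r$has_ncrna_hit) "ncrna_hit",
               if (r$longest_orf_aa >= max_orf_aa)
                 sprintf("orf>=%daa", max_orf_aa))
    paste(parts, collapse = ";")
  }, "")
  res[non_cand, "stage_reached"] <- "coding"
  res[non_cand, "filter_reasons"] <- reasons
  res[cand_ids, "stage_reached"] <- "candidate"

  cand_ann <- ann[ann$transcript_id %in% cand_ids, , drop = FALSE]
  cutoff <- ncp_cutoff(cand_ann)
  pot_ids <- cand_ann$transcript_id[cand_ann$ncp > cutoff]
  low_ncp <- setdiff(cand_ids, pot_ids)
  res[low_ncp, "stage_reached"] <- "coding"
  res[low_ncp, "filter_reasons"] <- sprintf("ncp<=%.4f", cutoff)
  res[pot_ids, "stage_reached"] <- "potential"

  coding_ids <- setdiff(retained$transcripts$transcript_id, pot_ids)
  coding <- if (length(coding_ids)) subset_transcripts(retained, coding_ids)
    else NULL
  coding_universe <- if (!is.null(extra_coding) && !is.null(coding))
    bind_transcripts(coding, extra_coding)
  else if (!is.null(extra_coding)) extra_coding else coding
  if (is.null(coding_universe)) {
    empty_tx <- retained$transcripts[0, , drop = FALSE]
    coding_universe <- ts
    coding_universe$transcripts <- empty_tx
    coding_universe$exons <- retained$exons[0, , drop = FALSE]
  }
  coding_universe$transcripts$biotype <- "coding"

  potentials <- subset_transcripts(retained, pot_ids)
  pf <- positional_filter(potentials, coding_universe, downstream_bp)
  res[pf$removed$transcript_id, "filter_reasons"] <- pf$removed$reason
  lnc_ids <- pf$kept$transcripts$transcript_id
  res[lnc_ids, "stage_reached"] <- "lncRNA"

  linc_ids <- call_lincRNAs(pf$kept, coding_universe)
  res[linc_ids, "stage_reached"] <- "lincRNA"

  if (!is.null(cage)) {
    supp <- cage_support(retained, cage, cage_upstream, cage_downstream, min_tpm)
    res[names(supp), "cage_supported"] <- unname(supp)
  }

  lnc <- pf$kept
  if (nrow(lnc$transcripts)) {
    lnc$transcripts$biotype <- ifelse(
      lnc$transcripts$transcript_id %in% linc_ids, "lincRNA", "lncRNA")
  }
  linc <- if (length(linc_ids)) subset_transcripts(lnc, linc_ids) else {
    e <- lnc; e$transcripts <- lnc$transcripts[0, , drop = FALSE]
    e$exons <- lnc$exons[0, , drop = FALSE]; e
  }
  rownames(res) <- NULL
  list(results = res, lncRNAs = lnc, lincRNAs = linc,
       coding = coding_universe, ncp_cutoff = cutoff)
}
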