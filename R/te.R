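#' Loci with exonic transposable-element fragments
#'
#' For each biotype, counts the loci with at least one repeat overlapping
#' any of their exons by >= 1 bp (strand-agnostic; exons are merged per
#' locus first).
#'
#' @param ts a `transcript_set` with biotypes assigned
#' @param repeats repeat table (`chrom`, `start`, `end`, `te_class`,
#'   `te_family`)
#' @return data.frame per biotype: `n_loci`, `n_te_loci`, `percent`, and
#'   the per-locus hit table in attribute `"hits"`
#' @export
exonic_te_loci <- function(ts, repeats) {
  loc_of <- stats::setNames(ts$transcripts$locus_id,
                            ts$transcripts$transcript_id)
  bt_loc <- unique(data.frame(locus_id = ts$transcripts$locus_id,
                              biotype = ts$transcripts$biotype,
                              stringsAsFactors = FALSE))
  ex <- ts$exons
  ex$locus_id <- unname(loc_of[ex$transcript_id])
  hit_loci <- character()
  if (nrow(repeats) && nrow(ex)) {
    hits <- .overlap_hits(ex, repeats)
    hit_loci <- unique(ex$locus_id[hits$q])
  }
  res <- do.call(rbind, lapply(sort(unique(bt_loc$biotype)), function(bt) {
    loci <- unique(bt_loc$locus_id[bt_loc$biotype == bt])
    n_hit <- sum(loci %in% hit_loci)
    data.frame(biotype = bt, n_loci = length(loci), n_te_loci = n_hit,
               percent = 100 * n_hit / length(loci), stringsAsFactors = FALSE)
  }))
  attr(res, "hits") <- hit_loci
  res
}

# merged exonic space of a transcript set
.exon_space <- function(ts) merge_intervals(ts$exons)

#' TE coverage of exonic space per class or family
#'
#' Fraction of the merged exonic space covered by repeats of each TE class
#' (or family): covered bp of (merged exons intersected with merged repeats
#' of the class) over total merged exonic bp. Overlapping classes are
#' counted independently.
#'
#' @param ts a `transcript_set`
#' @param repeats repeat table
#' @param by `"te_class"` or `"te_family"`
#' @return data.frame with columns `group`, `covered_bp`, `fraction`
#' @export
te_coverage <- function(ts, repeats, by = c("te_class", "te_family")) {
  by <- match.arg(by)
  space <- .exon_space(ts)
  total <- sum(space$end - space$start)
  groups <- sort(unique(repeats[[by]]))
  res <- lapply(groups, function(g) {
    r <- merge_intervals(repeats[repeats[[by]] == g, , drop = FALSE])
    hits <- .overlap_hits(space, r)
    cov <- if (nrow(hits)) sum(overlap_length(space[hits$q, ], r[hits$s, ]))
      else 0
    data.frame(group = g, covered_bp = cov,
               fraction = if (total > 0) cov / total else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(group = character(), covered_bp = numeric(),
                      fraction = numeric())
  out
}

#' TE enrichment of a transcript set over the genomic average
#'
#' Per TE class or family, the log2 ratio of the fraction of the set's
#' merged exonic space covered by the TE group over the fraction of the
#' whole genome covered by it. Positive values indicate enrichment,
#' negative depletion. A set fraction of zero with a nonzero genomic
#' fraction is reported as `-Inf` with `status = "depleted_below_measurement"`;
#' groups absent from the genome are `NA` with `status = "undefined"`.
#'
#' @param ts a `transcript_set`
#' @param repeats repeat table
#' @param genome named numeric vector of chromosome lengths
#' @param by `"te_class"` or `"te_family"`
#' @return data.frame: `group`, `set_fraction`, `genome_fraction`, `ratio`,
#'   `log2_ratio`, `status`
#' @export
te_enrichment <- function(ts, repeats, genome, by = c("te_class", "te_family")) {
  by <- match.arg(by)
  cov <- te_coverage(ts, repeats, by)
  genome_bp <- sum(genome)
  res <- lapply(seq_len(nrow(cov)), function(i) {
    g <- cov$group[i]
    gbp <- covered_bases(repeats[repeats[[by]] == g, , drop = FALSE])
    gfrac <- gbp / genome_bp
    sfrac <- cov$fraction[i]
    if (gfrac == 0) {
      data.frame(group = g, set_fraction = sfrac, genome_fraction = 0,
                 ratio = NA_real_, log2_ratio = NA_real_,
                 status = "undefined", stringsAsFactors = FALSE)
    } else if (sfrac == 0) {
      data.frame(group = g, set_fraction = 0, genome_fraction = gfrac,
                 ratio = 0, log2_ratio = -Inf,
                 status = "depleted_below_measurement", stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, set_fraction = sfrac, genome_fraction = gfrac,
                 ratio = sfrac / gfrac, log2_ratio = log2(sfrac / gfrac),
                 status = "ok", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(group = character(), set_fraction = numeric(),
                      genome_fraction = numeric(), ratio = numeric(),
                      log2_ratio = numeric(), status = character())
  out
}

#' Start-site-associated transposable elements
#'
#' A transcript is TSS-associated with a repeat when the repeat interval
#' contains the transcript's 5'-terminal base: the start coordinate for
#' plus-strand transcripts, the last base before the end coordinate for
#' minus-strand transcripts.
#'
#' @param ts a `transcript_set`
#' @param repeats repeat table with `te_class`
#' @return data.frame per transcript: `transcript_id`, `tss_associated`,
#'   `te_class` of the covering repeat (first by coordinate; `NA` if none)
#' @export
tss_associated_te <- function(ts, repeats) {
  tx <- ts$transcripts
  tss <- tss_position(ts)
  res <- data.frame(transcript_id = tx$transcript_id,
                    tss_associated = FALSE, te_class = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tx))) {
    hit <- repeats$chrom == tx$chrom[i] & repeats$start <= tss[i] &
      repeats$end > tss[i]
    if (any(hit)) {
      res$tss_associated[i] <- TRUE
      first <- which(hit)[order(repeats$start[hit])][1]
      res$te_class[i] <- repeats$te_class[first]
    }
  }
  res
}
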