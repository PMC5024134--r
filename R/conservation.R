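#' Exon-level conservation scores from alignment blocks
#'
#' For every exon and every overlapping alignment-block element in the
#' focal species, the contribution is
#' `similarity * overlap / block_length`; exon scores sum the contributions
#' and transcript scores sum their exons. Scores are additive over exons and
#' linear in the block similarity.
#'
#' @param ts a `transcript_set`
#' @param blocks data.frame of block elements for the focal species:
#'   `block_id`, `chrom`, `start`, `end`, `score`
#' @return list with `transcript_scores` (named numeric vector per
#'   transcript, 0 when nothing overlaps) and `exon_contributions`
#'   (data.frame with one row per exon/block overlap)
#' @export
score_conservation <- function(ts, blocks) {
  ex <- ts$exons
  scores <- stats::setNames(numeric(nrow(ts$transcripts)),
                            ts$transcripts$transcript_id)
  hits <- .overlap_hits(ex, blocks)
  if (nrow(hits) == 0)
    return(list(transcript_scores = scores,
                exon_contributions = data.frame(
                  transcript_id = character(), exon_index = integer(),
                  block_id = character(), contribution = numeric())))
  ovl <- overlap_length(ex[hits$q, ], blocks[hits$s, ])
  blen <- blocks$end[hits$s] - blocks$start[hits$s]
  contrib <- blocks$score[hits$s] * ovl / blen
  df <- data.frame(transcript_id = ex$transcript_id[hits$q],
                   exon_index = hits$q,
                   block_id = blocks$block_id[hits$s],
                   contribution = contrib, stringsAsFactors = FALSE)
  agg <- tapply(df$contribution, df$transcript_id, sum)
  scores[names(agg)] <- agg
  list(transcript_scores = scores, exon_contributions = df)
}

#' Call lncRNAs conserved across species from shared alignment blocks
#'
#' A block qualifies when it has elements in every required species and each
#' element overlaps an exon of some lncRNA in its species; the block then
#' links the overlapping lncRNAs, which are all called conserved. Supports
#' the two-species (teleost) and four-species (vertebrate) modes.
#'
#' @param lnc_by_species named list of `transcript_set`s, one per species
#' @param blocks data.frame (`block_id`, `species`, `chrom`, `start`, `end`,
#'   `score`) of per-species block elements
#' @param required_species species that must all be present and overlapping;
#'   default all names of `lnc_by_species`
#' @param min_overlap minimum exon overlap in bp (default 1)
#' @return list with `links` (data.frame `block_id`, `species`,
#'   `transcript_id`) and `conserved` (named list of conserved transcript
#'   ids per species)
#' @export
call_conserved_lncRNAs <- function(lnc_by_species, blocks,
                                   required_species = names(lnc_by_species),
                                   min_overlap = 1) {
  stopifnot(length(required_species) >= 2,
            all(required_species %in% names(lnc_by_species)))
  blocks <- blocks[blocks$species %in% required_species, , drop = FALSE]
  full <- names(which(tapply(blocks$species, blocks$block_id, function(x)
    all(required_species %in% x))))
  blocks <- blocks[blocks$block_id %in% full, , drop = FALSE]
  links <- data.frame(block_id = character(), species = character(),
                      transcript_id = character(), stringsAsFactors = FALSE)
  if (nrow(blocks)) {
    per_sp <- lapply(required_species, function(sp) {
      b <- blocks[blocks$species == sp, , drop = FALSE]
      ex <- lnc_by_species[[sp]]$exons
      hits <- .overlap_hits(b, ex)
      if (nrow(hits)) {
        ovl <- overlap_length(b[hits$q, ], ex[hits$s, ])
        hits <- hits[ovl >= min_overlap, , drop = FALSE]
      }
      data.frame(block_id = b$block_id[hits$q],
                 species = rep(sp, nrow(hits)),
                 transcript_id = ex$transcript_id[hits$s],
                 stringsAsFactors = FALSE)
    })
    cand <- do.call(rbind, per_sp)
    cand <- unique(cand)
    # keep only blocks overlapping a lncRNA exon in EVERY required species
    ok <- names(which(tapply(cand$species, cand$block_id, function(x)
      all(required_species %in% x))))
    links <- cand[cand$block_id %in% ok, , drop = FALSE]
    rownames(links) <- NULL
  }
  conserved <- lapply(stats::setNames(required_species, required_species),
                      function(sp)
                        sort(unique(links$transcript_id[links$species == sp])))
  list(links = links, conserved = conserved)
}

#' Empirical conservation background by coordinate shuffling
#'
#' Repeatedly relocates the transcripts genome-wide (preserving exon/intron
#' structure, avoiding the exclusion regions), recomputes a summary of the
#' conservation signal per replicate, and returns the null distribution with
#' an add-one empirical p-value
#' `(1 + #{replicates >= observed}) / (1 + n_reps)`.
#'
#' @param ts a `transcript_set` (the observed features)
#' @param genome named numeric vector of chromosome lengths
#' @param blocks block elements for the focal species (see
#'   [score_conservation()])
#' @param exclude data.frame of intervals shuffled features must avoid
#' @param n_reps number of shuffle replicates
#' @param seed integer seed (replicate r uses `seed + r`)
#' @param statistic function mapping a `transcript_set` to a scalar summary;
#'   default mean conservation score
#' @return list with `observed`, `null` (numeric vector of length
#'   `n_reps`), and `p_value`
#' @export
conservation_background <- function(ts, genome, blocks, exclude = NULL,
                                    n_reps = 100, seed = 1,
                                    statistic = NULL) {
  if (is.null(statistic))
    statistic <- function(x) mean(score_conservation(x, blocks)$transcript_scores)
  observed <- statistic(ts)
  null <- vapply(seq_len(n_reps), function(r) {
    shuf <- .with_seed(seed + r, shuffle_transcripts(ts, genome, exclude))
    statistic(shuf)
  }, 0)
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (1 + n_reps))
}
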