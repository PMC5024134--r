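#' Construct a set of transcript models
#'
#' The central container of the package: a collection of stranded, multi-exon
#' gene models. All coordinates are 0-based half-open (BED convention);
#' conversion to and from 1-based closed GTF coordinates happens only in
#' [read_gtf()] and [write_gtf()].
#'
#' @param transcripts data.frame with columns `transcript_id`, `locus_id`,
#'   `chrom`, `start`, `end`, `strand` and optionally `biotype` (one of
#'   `"coding"`, `"lncRNA"`, `"lincRNA"`, `"unclassified"`). `start`/`end`
#'   may be omitted, in which case they are derived from the exons.
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`; one row per exon. Exons are sorted by start within
#'   each transcript and must be non-overlapping.
#' @return An object of class `transcript_set`: a list with elements
#'   `transcripts` and `exons`, both data.frames.
#' @export
transcript_set <- function(transcripts, exons) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  need_tx <- c("transcript_id", "locus_id", "chrom", "strand")
  need_ex <- c("transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need_tx, names(transcripts))
  if (length(miss)) stop("transcripts lacks column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_ex, names(exons))
  if (length(miss)) stop("exons lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id in transcript table")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon rows reference unknown transcript_id")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("transcript strand must be '+' or '-'")
  if (any(exons$start < 0) || any(exons$end <= exons$start))
    stop("exon intervals must satisfy 0 <= start < end")

  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  # derive/refresh spans from exons
  agg_min <- tapply(exons$start, exons$transcript_id, min)
  agg_max <- tapply(exons$end, exons$transcript_id, max)
  if (!all(transcripts$transcript_id %in% names(agg_min)))
    stop("every transcript needs at least one exon")
  transcripts$start <- as.numeric(agg_min[transcripts$transcript_id])
  transcripts$end <- as.numeric(agg_max[transcripts$transcript_id])
  if (!"biotype" %in% names(transcripts)) transcripts$biotype <- "unclassified"
  transcripts$biotype <- as.character(transcripts$biotype)
  bad <- setdiff(unique(transcripts$biotype),
                 c("coding", "lncRNA", "lincRNA", "unclassified"))
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))
  rownames(transcripts) <- NULL

  # per-transcript consistency: same chrom/strand, non-overlapping exons
  sp <- split(exons, exons$transcript_id)
  tx_chrom <- stats::setNames(transcripts$chrom, transcripts$transcript_id)
  tx_strand <- stats::setNames(transcripts$strand, transcripts$transcript_id)
  for (id in names(sp)) {
    e <- sp[[id]]
    if (any(e$chrom != tx_chrom[[id]]) || any(e$strand != tx_strand[[id]]))
      stop("exons of ", id, " disagree with transcript chrom/strand")
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", id)
  }

  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$locus_id)), "loci,",
      nrow(x$exons), "exons\n")
  tb <- table(x$transcripts$biotype)
  cat("  biotypes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of exons per transcript
#' @param ts a `transcript_set`
#' @return named integer vector, in transcript table order
#' @export
n_exons <- function(ts) {
  tab <- table(ts$exons$transcript_id)
  out <- as.integer(tab[ts$transcripts$transcript_id])
  names(out) <- ts$transcripts$transcript_id
  out
}

#' Mature transcript lengths (summed exon widths, nt)
#' @param ts a `transcript_set`
#' @return named numeric vector, in transcript table order
#' @export
transcript_lengths <- function(ts) {
  w <- tapply(ts$exons$end - ts$exons$start, ts$exons$transcript_id, sum)
  out <- as.numeric(w[ts$transcripts$transcript_id])
  names(out) <- ts$transcripts$transcript_id
  out
}

#' Intron intervals of a transcript set
#'
#' Introns are the gaps between consecutive exons of the same transcript.
#' @param ts a `transcript_set`
#' @return data.frame with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`; zero rows for mono-exonic input.
#' @export
intron_intervals <- function(ts) {
  e <- ts$exons
  if (nrow(e) == 0)
    return(data.frame(transcript_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character()))
  same <- c(FALSE, e$transcript_id[-1] == e$transcript_id[-nrow(e)])
  idx <- which(same)
  data.frame(transcript_id = e$transcript_id[idx],
             chrom = e$chrom[idx],
             start = e$end[idx - 1],
             end = e$start[idx],
             strand = e$strand[idx],
             stringsAsFactors = FALSE)
}

#' Locus spans of a transcript set
#'
#' @param ts a `transcript_set`
#' @return data.frame with one row per locus: `locus_id`, `chrom`, `start`,
#'   `end`, `strand` (`"."` when transcripts of the locus disagree) and
#'   `biotype` (the "highest" biotype among member transcripts, where
#'   coding > lncRNA > lincRNA > unclassified for labelling purposes).
#' @export
locus_spans <- function(ts) {
  tx <- ts$transcripts
  f <- factor(tx$locus_id)
  rank <- c(coding = 1, lncRNA = 2, lincRNA = 3, unclassified = 4)
  out <- data.frame(
    locus_id = levels(f),
    chrom = as.character(tapply(tx$chrom, f, `[`, 1)),
    start = as.numeric(tapply(tx$start, f, min)),
    end = as.numeric(tapply(tx$end, f, max)),
    strand = as.character(tapply(tx$strand, f, function(x)
      if (length(unique(x)) == 1) x[1] else ".")),
    biotype = as.character(tapply(tx$biotype, f, function(x) {
      u <- unique(x); u[which.min(rank[u])]
    })),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 5' start (TSS) coordinate of each transcript
#'
#' The position of the 5'-terminal base: `start` for plus-strand transcripts
#' and `end - 1` for minus-strand transcripts (0-based).
#' @param ts a `transcript_set`
#' @return named numeric vector, in transcript table order
#' @export
tss_position <- function(ts) {
  tx <- ts$transcripts
  out <- ifelse(tx$strand == "+", tx$start, tx$end - 1)
  names(out) <- tx$transcript_id
  out
}

#' Subset a transcript set by transcript ids
#' @param ts a `transcript_set`
#' @param ids transcript ids to keep
#' @return a `transcript_set`
#' @export
subset_transcripts <- function(ts, ids) {
  tx <- ts$transcripts[ts$transcripts$transcript_id %in% ids, , drop = FALSE]
  ex <- ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE]
  transcript_set(tx, ex)
}

#' Combine transcript sets
#' @param ... `transcript_set` objects with disjoint transcript ids
#' @return a `transcript_set`
#' @export
bind_transcripts <- function(...) {
  parts <- list(...)
  transcript_set(do.call(rbind, lapply(parts, function(p) p$transcripts)),
                 do.call(rbind, lapply(parts, function(p) p$exons)))
}
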