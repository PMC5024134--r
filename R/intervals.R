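#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# internal: data.frame of 0-based half-open intervals -> GRanges (1-based
# closed); `levels` fixes a shared seqlevel set when two objects are compared
.as_granges <- function(df, levels = NULL) {
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", nrow(df))
  strand[strand == "."] <- "*"
  seq <- if (is.null(levels)) df$chrom else factor(df$chrom, levels = levels)
  GenomicRanges::GRanges(seqnames = seq,
                         ranges = IRanges::IRanges(start = df$start + 1,
                                                   end = df$end),
                         strand = strand)
}

.from_granges <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Construct a table of genomic intervals
#'
#' @param chrom chromosome names
#' @param start,end 0-based half-open coordinates, `0 <= start < end`
#' @param strand `"+"`, `"-"` or `"."` (unstranded)
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`
#' @export
genome_intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("intervals must satisfy 0 <= start < end")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  df
}

#' Merge intervals into a minimal non-redundant set
#'
#' Collapses a set of genomic intervals into the minimal set of maximal
#' non-overlapping intervals covering the same bases (the non-redundant set
#' used for exon/repeat space computations). Abutting half-open intervals
#' (`[a,b)` and `[b,c)`) are merged.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (and `strand`)
#' @param stranded if `TRUE`, merge only within strand
#' @return data.frame of merged intervals, sorted by chrom then start
#' @export
merge_intervals <- function(intervals, stranded = FALSE) {
  if (nrow(intervals) == 0) return(genome_intervals(character(), numeric(), numeric())[0, ])
  if (!stranded) {
    intervals <- intervals
    intervals$strand <- "."
  }
  gr <- .as_granges(intervals)
  merged <- GenomicRanges::reduce(gr, ignore.strand = !stranded)
  out <- .from_granges(merged)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap length of two intervals
#'
#' `max(0, min(end) - max(start))` in bp when the chromosomes match, else 0.
#' Vectorised over rows; strand is ignored.
#'
#' @param a,b data.frames (or single rows) with `chrom`, `start`, `end`
#' @return numeric vector of overlap lengths in bp
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ch_a <- rep_len(a$chrom, n); ch_b <- rep_len(b$chrom, n)
  ov <- pmin(rep_len(a$end, n), rep_len(b$end, n)) -
    pmax(rep_len(a$start, n), rep_len(b$start, n))
  ifelse(ch_a == ch_b, pmax(0, ov), 0)
}

#' Gap between two intervals
#'
#' Distance in bp between two intervals on the same chromosome; 0 when they
#' overlap or abut. `Inf` for different chromosomes.
#' @param a,b data.frames with `chrom`, `start`, `end`
#' @return numeric vector of gaps
#' @export
interval_gap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  g <- pmax(rep_len(a$start, n), rep_len(b$start, n)) -
    pmin(rep_len(a$end, n), rep_len(b$end, n))
  out <- pmax(0, g)
  out[rep_len(a$chrom, n) != rep_len(b$chrom, n)] <- Inf
  out
}

#' Transcripts within a window of a query transcript
#'
#' Returns the subject transcripts whose span overlaps the query span
#' extended by `window` bp on both sides (window-extension semantics: a
#' subject at a gap strictly smaller than `window` is included). Strand is
#' ignored.
#'
#' @param query single-row data.frame with `chrom`, `start`, `end` (e.g. one
#'   row of a `transcript_set` transcript table)
#' @param subjects data.frame of candidate neighbours (same columns)
#' @param window non-negative window size in bp
#' @return the overlapping rows of `subjects`
#' @export
window_neighbors <- function(query, subjects, window) {
  stopifnot(window >= 0, nrow(query) == 1)
  hit <- subjects$chrom == query$chrom &
    subjects$start < query$end + window &
    subjects$end > query$start - window
  subjects[hit, , drop = FALSE]
}

#' All pairs of features within a window
#'
#' Bulk version of [window_neighbors()]: every (query, subject) pair whose
#' spans lie within `window` bp of each other (gap strictly smaller than the
#' window, 0 if overlapping). Used for the proximal-gene analyses.
#'
#' @param queries,subjects data.frames with `chrom`, `start`, `end` and an id
#'   column named by `q_id`/`s_id`
#' @param window window size in bp
#' @param q_id,s_id names of the id columns
#' @return data.frame with columns `query`, `subject`
#' @export
window_pairs <- function(queries, subjects, window, q_id = "transcript_id",
                         s_id = "transcript_id") {
  if (nrow(queries) == 0 || nrow(subjects) == 0)
    return(data.frame(query = character(), subject = character()))
  qx <- queries
  qx$start <- pmax(0, qx$start - window)
  qx$end <- qx$end + window
  lv <- union(unique(qx$chrom), unique(subjects$chrom))
  hits <- GenomicRanges::findOverlaps(.as_granges(qx, lv),
                                      .as_granges(subjects, lv),
                                      ignore.strand = TRUE)
  data.frame(query = queries[[q_id]][S4Vectors::queryHits(hits)],
             subject = subjects[[s_id]][S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

# internal: overlap hits between two interval tables (>= 1 bp, strand-blind
# unless stranded = TRUE). Returns data.frame of row indices (q, s).
.overlap_hits <- function(a, b, stranded = FALSE) {
  if (nrow(a) == 0 || nrow(b) == 0) return(data.frame(q = integer(), s = integer()))
  lv <- union(unique(a$chrom), unique(b$chrom))
  hits <- GenomicRanges::findOverlaps(.as_granges(a, lv), .as_granges(b, lv),
                                      ignore.strand = !stranded)
  data.frame(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
}

#' Total bases covered by a set of intervals
#' @param intervals data.frame with `chrom`, `start`, `end`
#' @return total merged length in bp
#' @export
covered_bases <- function(intervals) {
  m <- merge_intervals(intervals)
  sum(m$end - m$start)
}

#' Shuffle transcripts genome-wide with exclusion regions
#'
#' Relocates every transcript to a uniformly random position on the genome,
#' preserving its chromosome-independent exon/intron structure, length and
#' strand, such that the relocated span does not intersect any exclusion
#' interval. Chromosomes are chosen with probability proportional to their
#' length; placement is rejection-sampled against the exclusion set. This
#' emulates coordinate shuffling with an exclusion file as used for empirical
#' background distributions.
#'
#' @param ts a `transcript_set`
#' @param genome named numeric vector of chromosome lengths (bp)
#' @param exclude data.frame of intervals the shuffled spans must not touch
#'   (typically coding and lncRNA locus spans)
#' @param max_tries placement attempts per transcript before failing
#' @return a `transcript_set` with identical structure at new coordinates
#' @export
shuffle_transcripts <- function(ts, genome, exclude = NULL, max_tries = 1000) {
  stopifnot(length(genome) > 0, all(genome > 0))
  excl <- if (!is.null(exclude) && nrow(exclude)) merge_intervals(exclude) else NULL
  excl_by_chrom <- if (is.null(excl)) list() else split(excl, excl$chrom)
  chroms <- names(genome)
  tx <- ts$transcripts
  ex <- ts$exons
  new_tx <- tx
  new_ex <- ex
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    eri <- which(ex$transcript_id == id)
    offs <- ex$start[eri] - tx$start[i]
    ends <- ex$end[eri] - tx$start[i]
    span <- tx$end[i] - tx$start[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(chroms, 1, prob = genome)
      room <- genome[[chrom]] - span
      if (room < 0) next
      pos <- floor(stats::runif(1, 0, room + 1))
      ec <- excl_by_chrom[[chrom]]
      if (!is.null(ec) && any(ec$start < pos + span & ec$end > pos)) next
      new_tx$chrom[i] <- chrom
      new_tx$start[i] <- pos
      new_tx$end[i] <- pos + span
      new_ex$chrom[eri] <- chrom
      new_ex$start[eri] <- pos + offs
      new_ex$end[eri] <- pos + ends
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place transcript ", id,
                  " after ", max_tries, " tries (genome too constrained)")
  }
  # structure is shift-preserved, so the validated container can be rebuilt
  # directly
  structure(list(transcripts = new_tx, exons = new_ex),
            class = "transcript_set")
}
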