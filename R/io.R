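#' Read transcript models from a GTF file
#'
#' Parses `exon` features of an Ensembl-dialect GTF. GTF 1-based closed
#' coordinates are converted to the package-internal 0-based half-open
#' convention; exons are grouped by `transcript_id` (locus taken from
#' `gene_id`) and sorted by start. Features other than `exon` and comment
#' lines are ignored. An optional `biotype` attribute is honoured.
#'
#' @param path path to a GTF file
#' @return a [transcript_set()]
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 9L)
  if (length(bad))
    stop("malformed GTF line ", lineno[bad[1]], " in ", path,
         " (expected 9 tab-separated fields)")
  feat <- vapply(fields, `[[`, "", 3L)
  idx <- which(feat == "exon")
  if (!length(idx)) stop("no exon features in ", path)
  getattr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  attrs <- vapply(fields[idx], `[[`, "", 9L)
  tid <- getattr(attrs, "transcript_id")
  if (anyNA(tid))
    stop("exon without transcript_id at GTF line ", lineno[idx[which(is.na(tid))[1]]])
  gid <- getattr(attrs, "gene_id")
  if (anyNA(gid))
    stop("exon without gene_id at GTF line ", lineno[idx[which(is.na(gid))[1]]])
  bt <- getattr(attrs, "biotype")
  bt[is.na(bt)] <- "unclassified"
  ex <- data.frame(
    transcript_id = tid,
    chrom = vapply(fields[idx], `[[`, "", 1L),
    start = as.numeric(vapply(fields[idx], `[[`, "", 4L)) - 1,
    end = as.numeric(vapply(fields[idx], `[[`, "", 5L)),
    strand = vapply(fields[idx], `[[`, "", 7L),
    stringsAsFactors = FALSE)
  first <- !duplicated(tid)
  tx <- data.frame(transcript_id = tid[first], locus_id = gid[first],
                   chrom = ex$chrom[first], strand = ex$strand[first],
                   biotype = bt[first], stringsAsFactors = FALSE)
  transcript_set(tx, ex)
}

#' Write transcript models as GTF
#'
#' Emits one `exon` feature per exon in Ensembl dialect, converting internal
#' 0-based half-open coordinates back to 1-based closed. Output is canonical:
#' transcripts in table order, exons by ascending start, fixed attribute
#' order (`gene_id`, `transcript_id`, `biotype`), so that
#' `write_gtf(read_gtf(f))` reproduces a file written by this function byte
#' for byte.
#'
#' @param ts a `transcript_set`
#' @param path output path
#' @param source value for the GTF source column
#' @return `path`, invisibly
#' @export
write_gtf <- function(ts, path, source = "lncdev") {
  tx <- ts$transcripts
  ex <- ts$exons[order(match(ts$exons$transcript_id, tx$transcript_id),
                       ts$exons$start), , drop = FALSE]
  locus <- stats::setNames(tx$locus_id, tx$transcript_id)
  bt <- stats::setNames(tx$biotype, tx$transcript_id)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s";',
    ex$chrom, source, as.integer(ex$start + 1), as.integer(ex$end), ex$strand,
    locus[ex$transcript_id], ex$transcript_id, bt[ex$transcript_id])
  writeLines(lines, path)
  invisible(path)
}

#' Read a refFlat gene model table
#'
#' Reader for the UCSC refFlat flat format (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds).
#' refFlat coordinates are already 0-based half-open.
#'
#' @param path path to a refFlat file (no header)
#' @return a [transcript_set()]
#' @export
read_refflat <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 11) stop("refFlat file must have 11 columns")
  names(df)[1:11] <- c("gene", "name", "chrom", "strand", "txStart", "txEnd",
                       "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  split_num <- function(x) lapply(strsplit(x, ","), as.numeric)
  es <- split_num(df$exonStarts)
  ee <- split_num(df$exonEnds)
  ex <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(transcript_id = df$name[i], chrom = df$chrom[i],
               start = es[[i]], end = ee[[i]], strand = df$strand[i],
               stringsAsFactors = FALSE)
  }))
  tx <- data.frame(transcript_id = df$name, locus_id = df$gene,
                   chrom = df$chrom, strand = df$strand,
                   stringsAsFactors = FALSE)
  transcript_set(tx, ex)
}

#' Write intervals as BED6
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` columns
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed6 <- function(intervals, path) {
  n <- nrow(intervals)
  name <- if ("name" %in% names(intervals)) intervals$name else rep(".", n)
  score <- if ("score" %in% names(intervals)) intervals$score else rep(0, n)
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", n)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     name, format(score, trim = TRUE), strand), path)
  invisible(path)
}

#' Write a transcript set as BED12
#' @param ts a `transcript_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed12 <- function(ts, path) {
  tx <- ts$transcripts
  sp <- split(ts$exons, ts$exons$transcript_id)
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    e <- sp[[tx$transcript_id[i]]]
    e <- e[order(e$start), , drop = FALSE]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            tx$chrom[i], as.integer(tx$start[i]), as.integer(tx$end[i]),
            tx$transcript_id[i], tx$strand[i],
            as.integer(tx$start[i]), as.integer(tx$start[i]), nrow(e),
            paste0(as.integer(e$end - e$start), collapse = ","),
            paste0(as.integer(e$start - tx$start[i]), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# internal: header-checked TSV reader
.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, " lacks required column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a per-transcript annotation table
#'
#' Expects the evidence columns produced by an upstream annotation pipeline:
#' homology flags, longest-ORF length in amino acids, non-coding potential
#' (NCP) in `[0, 1]`, SwissProt flag and comma-separated GO terms.
#' @param path TSV with header
#' @return data.frame
#' @export
read_annotation_table <- function(path) {
  df <- .read_tsv(path, c("transcript_id", "has_protein_hit", "has_domain_hit",
                          "has_ncrna_hit", "longest_orf_aa", "ncp",
                          "has_swissprot_hit"))
  for (col in c("has_protein_hit", "has_domain_hit", "has_ncrna_hit",
                "has_swissprot_hit"))
    df[[col]] <- as.logical(df[[col]])
  if (any(df$ncp < 0 | df$ncp > 1)) stop("ncp must lie in [0, 1]")
  if (any(df$longest_orf_aa < 0)) stop("longest_orf_aa must be >= 0")
  df
}

#' Read a CAGE tag table
#' @param path TSV with header columns `chrom`, `pos` (0-based position of
#'   the tag), `strand`, `tpm`
#' @return data.frame
#' @export
read_cage_table <- function(path) {
  df <- .read_tsv(path, c("chrom", "pos", "strand", "tpm"))
  if (any(df$tpm < 0)) stop("tpm must be non-negative")
  df
}

#' Read a repeat element table
#' @param path TSV with header columns `chrom`, `start`, `end`, `repeat_id`,
#'   `strand`, `te_class`, `te_family`
#' @return data.frame
#' @export
read_repeat_table <- function(path) {
  .read_tsv(path, c("chrom", "start", "end", "repeat_id", "strand",
                    "te_class", "te_family"))
}

#' Read an orthology table for a species pair
#' @param path TSV with header columns `gene_a`, `gene_b`
#' @return data.frame
#' @export
read_orthology_table <- function(path) .read_tsv(path, c("gene_a", "gene_b"))

#' Read multi-species alignment blocks
#'
#' Blocks are a tabular reduction of a multiple alignment: one row per
#' species element, sharing a `block_id` and one `score` per block.
#' @param path TSV with header columns `block_id`, `species`, `chrom`,
#'   `start`, `end`, `score`
#' @return data.frame
#' @export
read_alignment_blocks <- function(path) {
  df <- .read_tsv(path, c("block_id", "species", "chrom", "start", "end", "score"))
  if (any(df$score <= 0)) stop("block scores must be positive")
  df
}

#' Construct a raw count matrix with library sizes
#'
#' @param counts integer matrix, transcripts in rows (rownames = transcript
#'   ids), stages in columns (colnames = stage names)
#' @param library_sizes total mapped reads per stage; defaults to column sums
#' @return object of class `count_matrix`
#' @export
count_matrix <- function(counts, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript rownames and stage colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(library_sizes) != ncol(counts))
    stop("one library size per stage required")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  names(library_sizes) <- colnames(counts)
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "stages (", paste(colnames(x$counts), collapse = ", "), ")\n")
  cat("  library sizes:", paste(format(x$library_sizes, trim = TRUE),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Read a raw count matrix from TSV
#' @param path TSV with header; first column `transcript_id`, remaining
#'   columns one per stage
#' @param library_sizes optional per-stage totals; default column sums
#' @return a [count_matrix()]
#' @export
read_count_matrix <- function(path, library_sizes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "transcript_id")
    stop("first column of ", path, " must be transcript_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  count_matrix(m, library_sizes)
}

#' Write a count matrix to TSV
#' @param cm a [count_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(transcript_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
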