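#' Fisher-exact GO term enrichment
#'
#' One-sided (over-representation) Fisher exact test per GO term on the
#' 2x2 table (in set & has term, in set & lacks term, background-only & has
#' term, background-only & lacks term), for terms with at least
#' `min_members` representatives in the set, with Benjamini-Hochberg FDR
#' across tested terms.
#'
#' @param set_ids ids of the set of interest (must be a subset of the
#'   background)
#' @param background_ids ids of the background universe
#' @param go_map data.frame with columns `id` and `go_term` (one row per
#'   annotation)
#' @param min_members minimum set representatives for a term to be tested
#'   (default 5)
#' @param fdr_max significance threshold on the FDR (default 0.05,
#'   inclusive); sets the `significant` flag only, all tested terms are
#'   returned
#' @param alternative `"greater"` (default, over-representation) or
#'   `"two.sided"`
#' @return data.frame per tested term: `go_term`, `k_in_set`, `n_set`,
#'   `K_in_background`, `N_background`, `percent_of_set`, `odds_ratio`,
#'   `p`, `fdr`, `significant`, sorted by p
#' @export
fisher_go_enrichment <- function(set_ids, background_ids, go_map,
                                 min_members = 5, fdr_max = 0.05,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  set_ids <- unique(set_ids)
  background_ids <- unique(background_ids)
  if (!all(set_ids %in% background_ids))
    stop("set ids must be a subset of the background")
  gm <- unique(go_map[go_map$id %in% background_ids, c("id", "go_term")])
  n_set <- length(set_ids)
  N <- length(background_ids)
  in_set <- gm$id %in% set_ids
  k_tab <- table(gm$go_term[in_set])
  terms <- names(k_tab)[k_tab >= min_members]
  if (!length(terms))
    return(data.frame(go_term = character(), k_in_set = integer(),
                      n_set = integer(), K_in_background = integer(),
                      N_background = integer(), percent_of_set = numeric(),
                      odds_ratio = numeric(), p = numeric(), fdr = numeric(),
                      significant = logical()))
  res <- do.call(rbind, lapply(terms, function(tm) {
    K <- sum(gm$go_term == tm)
    k <- as.integer(k_tab[[tm]])
    tab <- matrix(c(k, n_set - k, K - k, (N - n_set) - (K - k)), 2, 2)
    ft <- stats::fisher.test(tab, alternative = alternative)
    data.frame(go_term = tm, k_in_set = k, n_set = n_set,
               K_in_background = K, N_background = N,
               percent_of_set = 100 * k / n_set,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr <= fdr_max
  res[order(res$p, res$go_term), , drop = FALSE]
}

#' GO enrichment of coding genes proximal to a lincRNA subset
#'
#' Builds the test set as the coding transcripts lying within `window` bp of
#' the lincRNAs of interest and the background as the coding transcripts
#' within `window` bp of the whole lincRNA set, then runs
#' [fisher_go_enrichment()].
#'
#' @param lincs_of_interest,all_lincs `transcript_set`s (e.g. embryonic
#'   lincRNAs and all lincRNAs)
#' @param coding `transcript_set` of coding models
#' @param go_map data.frame with `id` (coding transcript ids) and `go_term`
#' @param window pairing distance in bp (default 10000)
#' @param ... passed to [fisher_go_enrichment()]
#' @return the enrichment table (see [fisher_go_enrichment()])
#' @export
proximal_go_enrichment <- function(lincs_of_interest, all_lincs, coding,
                                   go_map, window = 10000, ...) {
  set_pairs <- window_pairs(lincs_of_interest$transcripts,
                            coding$transcripts, window)
  bg_pairs <- window_pairs(all_lincs$transcripts, coding$transcripts, window)
  fisher_go_enrichment(unique(set_pairs$subject), unique(bg_pairs$subject),
                       go_map, ...)
}
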