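#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` containing `K` annotated ones.
#' Computed exactly in log space via `stats::phyper`.
#'
#' @param N population (background) size.
#' @param K successes in the population (term size within background).
#' @param n draws (query size).
#' @param k observed successes (overlap).
#' @return The exact upper-tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (!is_count(v)) stopf("hypergeom_tail needs non-negative integers")
  }
  if (K > N || n > N || k > min(K, n)) stopf("inconsistent counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a gene set by the hypergeometric test
#'
#' Flat over-representation analysis: for every term, the upper-tail
#' hypergeometric probability of the query/term overlap against the
#' background universe, BH-adjusted across tested terms and sorted by
#' p-value. Terms without background overlap are skipped. (GO and KEGG
#' enrichment are the same operation over different annotations.)
#'
#' @param query character vector of query gene IDs (subset of
#'   `background`).
#' @param annotation long tibble `term, gene`.
#' @param background character vector, the gene universe.
#' @return Tibble `term, term_size, query_size, overlap, p, padj, hits`
#'   (list-column of overlapping gene IDs), ordered by `p`.
#' @export
go_enrich <- function(query, annotation, background) {
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background)) {
    stopf("query must be a subset of the background")
  }
  annotation <- as_tibble(annotation) %>%
    filter(.data$gene %in% background) %>%
    distinct(.data$term, .data$gene)
  N <- length(background); n <- length(query)
  res <- annotation %>%
    group_by(.data$term) %>%
    summarise(term_size = n(),
              hits = list(intersect(.data$gene, query)),
              .groups = "drop") %>%
    mutate(query_size = n,
           overlap = purrr::map_int(.data$hits, length),
           p = purrr::map2_dbl(.data$term_size, .data$overlap,
                               function(K, k) hypergeom_tail(N, K, n, k)),
           padj = p.adjust(.data$p, method = "BH")) %>%
    arrange(.data$p, .data$term) %>%
    select("term", "term_size", "query_size", "overlap", "p", "padj",
           "hits")
  res
}

#' Species-specific enriched terms
#'
#' Terms significant (padj <= `alpha`) in the target species' enrichment
#' and not significant in any other species' enrichment over the same
#' term universe; reports the percentage of the target's significant
#' terms that are specific.
#'
#' @param enrichments named list of [go_enrich()] tables, one per
#'   species.
#' @param target species name whose specific terms are wanted.
#' @param alpha significance threshold on `padj`.
#' @return List with `specific` (character vector of term IDs) and
#'   `percent` (`NA` if the target has no significant terms).
#' @export
species_specific_bps <- function(enrichments, target, alpha = 0.05) {
  if (!target %in% names(enrichments)) stopf("unknown target species")
  sig <- lapply(enrichments, function(e) e$term[e$padj <= alpha])
  target_sig <- sig[[target]]
  if (length(target_sig) == 0) {
    return(list(specific = character(), percent = NA_real_))
  }
  other_sig <- unique(unlist(sig[setdiff(names(sig), target)]))
  specific <- setdiff(target_sig, other_sig)
  list(specific = specific,
       percent = 100 * length(specific) / length(target_sig))
}

#' Overlap test between two term sets
#'
#' Upper-tail hypergeometric probability of the observed overlap between
#' a candidate term set and another compartment's term set within a
#' common term universe. A small p means the candidate set is shared
#' with (not specific against) the other compartment.
#'
#' @param candidate,other character vectors of term IDs, both subsets of
#'   `universe`.
#' @param universe character vector, the term universe.
#' @return The p-value (1 for an empty candidate set).
#' @export
bp_overlap_test <- function(candidate, other, universe) {
  candidate <- unique(candidate); other <- unique(other)
  universe <- unique(universe)
  if (!all(candidate %in% universe) || !all(other %in% universe)) {
    stopf("term sets must be subsets of the universe")
  }
  if (length(candidate) == 0) return(1)
  hypergeom_tail(length(universe), length(intersect(other, universe)),
                 length(candidate), length(intersect(candidate, other)))
}
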