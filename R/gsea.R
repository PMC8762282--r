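#' Gene set enrichment score
#'
#' Classic Kolmogorov-Smirnov-style running sum over a ranked gene
#' list: set members ("hits") increment the sum by
#' `|score|^weight / sum of |score|^weight over hits`, non-members
#' decrement by `1 / (N - Nh)`. The enrichment score is the running-sum
#' value of largest magnitude, signed; when the positive and negative
#' extrema tie in magnitude the positive one is reported. When the set
#' spans the whole list the miss term is absent and the ES is +1 at the
#' last hit.
#'
#' @param ranked tibble with `gene` and `score` columns; sorted by
#'   decreasing score internally.
#' @param gene_set character vector; must intersect the ranked list.
#' @param weight exponent on |score| for hit increments (1 = weighted
#'   classic, 0 = unweighted KS).
#' @return A `gsea_result` object: list with `es`, `extremum_index`,
#'   `direction` (`"up"`/`"down"`), and `running` (tibble
#'   `index, gene, hit, running`).
#' @export
gsea_es <- function(ranked, gene_set, weight = 1) {
  ranked <- as_tibble(ranked) %>% arrange(desc(.data$score))
  genes <- ranked$gene
  hit <- genes %in% gene_set
  if (!any(hit)) stopf("gene set is disjoint from the ranked list")
  N <- length(genes); Nh <- sum(hit)
  w <- abs(ranked$score)^weight
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  if (Nh < N) inc[!hit] <- -1 / (N - Nh)
  running <- cumsum(inc)
  pos <- max(running); neg <- min(running)
  if (pos >= -neg - 1e-12) {  # magnitude tie prefers the positive extremum
    es <- pos; idx <- which.max(running)
  } else {
    es <- neg; idx <- which.min(running)
  }
  structure(list(es = es, extremum_index = idx,
                 direction = if (es >= 0) "up" else "down",
                 running = tibble(index = seq_len(N), gene = genes,
                                  hit = hit, running = running),
                 weight = weight, n = N, n_hits = Nh),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES %.4f (%s) at rank %d; %d/%d hits%s\n",
              x$es, x$direction, x$extremum_index, x$n_hits, x$n,
              if (!is.null(x$p)) sprintf("; perm p = %.4g", x$p) else ""))
  invisible(x)
}

#' @rdname gsea_es
#' @param x a `gsea_result`.
#' @param ... unused.
#' @export
tidy.gsea_result <- function(x, ...) x$running

#' @rdname gsea_es
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(es = x$es, direction = x$direction,
         extremum_index = x$extremum_index, n = x$n, n_hits = x$n_hits,
         p = x$p %||% NA_real_, n_perm = x$n_perm %||% NA_integer_)
}

#' Permutation p-value for a gene set enrichment score
#'
#' Gene-set label permutation: set membership is reshuffled over the
#' ranked list (size preserved) `n_perm` times, and
#' `p = (1 + #\{|ES_perm| >= |ES_obs|\}) / (n_perm + 1)` (add-one rule,
#' so p is never 0). Gene-set rather than phenotype permutation is used
#' because three replicates per group cannot support phenotype
#' permutation.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return The `gsea_result` of the observed set with `p` and `n_perm`
#'   attached.
#' @export
gsea_p <- function(ranked, gene_set, n_perm = 1000, weight = 1, seed = 1) {
  assert_count(n_perm, "n_perm", positive = TRUE)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  obs <- gsea_es(ranked, gene_set, weight)
  ranked <- as_tibble(ranked)
  genes <- ranked$gene
  Nh <- obs$n_hits
  withr::with_seed(seed, {
    perm_abs <- vapply(seq_len(n_perm), function(i) {
      abs(gsea_es(ranked, sample(genes, Nh), weight)$es)
    }, numeric(1))
  })
  obs$p <- (1 + sum(perm_abs >= abs(obs$es))) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs
}
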