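#' Spearman correlation with a defined degenerate case
#'
#' Pearson correlation of mid-ranks. Constant input has no defined rank
#' correlation and returns `NA_real_` (callers map it to maximum
#' distance).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stopf("need equal-length vectors of length >= 3")
  }
  if (pop_sd(x) < 1e-15 || pop_sd(y) < 1e-15) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Dynamic time warping over a precomputed cost matrix
#'
#' Classic DTW with the symmetric step pattern (1,1), (1,0), (0,1), unit
#' weights, full boundary constraints and no window: the returned path
#' starts at (1,1), ends at (m,n), and minimises the summed cell costs
#' globally. Ties during backtracking prefer the diagonal step, then the
#' vertical one.
#'
#' @param cost numeric matrix of finite, non-negative pairwise costs
#'   (query stages in rows, reference stages in columns).
#' @return A `stage_warp` object: list with `path` (tibble
#'   `query, reference, cost`), `total_cost`, and the input `cost`
#'   matrix. `total_cost` equals the sum of per-pair costs on the path.
#' @export
dtw_warp <- function(cost) {
  if (!is.matrix(cost) || length(cost) == 0) stopf("empty cost matrix")
  if (any(!is.finite(cost)) || any(cost < 0)) {
    stopf("costs must be finite and non-negative")
  }
  m <- nrow(cost); n <- ncol(cost)
  D <- matrix(Inf, m, n)
  D[1, 1] <- cost[1, 1]
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      if (i == 1 && j == 1) next
      best <- Inf
      if (i > 1 && j > 1) best <- min(best, D[i - 1, j - 1])
      if (i > 1) best <- min(best, D[i - 1, j])
      if (j > 1) best <- min(best, D[i, j - 1])
      D[i, j] <- cost[i, j] + best
    }
  }
  # backtrack, diagonal preferred, then vertical
  path <- list(c(m, n))
  i <- m; j <- n
  while (i > 1 || j > 1) {
    cand <- list()
    if (i > 1 && j > 1) cand$diag <- D[i - 1, j - 1]
    if (i > 1) cand$vert <- D[i - 1, j]
    if (j > 1) cand$horiz <- D[i, j - 1]
    pick <- names(cand)[which.min(unlist(cand))]  # list order = preference
    if (pick == "diag") { i <- i - 1; j <- j - 1 }
    else if (pick == "vert") i <- i - 1
    else j <- j - 1
    path[[length(path) + 1]] <- c(i, j)
  }
  path <- rev(path)
  path_tb <- tibble(query = map_int(path, 1),
                    reference = map_int(path, 2)) %>%
    mutate(cost = cost[cbind(.data$query, .data$reference)])
  structure(list(path = path_tb, total_cost = D[m, n], cost = cost),
            class = "stage_warp")
}

#' @export
print.stage_warp <- function(x, ...) {
  cat(sprintf("<stage_warp> %dx%d, total cost %.4f, path length %d\n",
              nrow(x$cost), ncol(x$cost), x$total_cost, nrow(x$path)))
  if (!is.null(x$best_match)) {
    cat("  best match: ",
        paste(sprintf("%s->%s", x$best_match$query_stage,
                      x$best_match$reference_stage), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Tidy a warp result
#'
#' @param x a `stage_warp` object.
#' @param ... unused.
#' @return The path as a tibble with per-pair costs (and stage labels
#'   when the warp came from [align_stages()]).
#' @export
tidy.stage_warp <- function(x, ...) x$path

#' Per-stage mean expression profiles for one species/compartment
#'
#' Averages replicates into one profile per developmental stage on the
#' log2(FPKM + 1) scale (or the stored log2 scale for batch-corrected
#' input), over whatever gene index the object carries — use the
#' ortholog-integrated matrix so profiles are comparable across species.
#'
#' @param es a [follicle_expr].
#' @param species,compartment which samples to profile.
#' @return List with `profiles` (genes x stages matrix) and `stages`
#'   (ordered stage labels).
#' @export
stage_series <- function(es, species, compartment) {
  meta <- es$sample_meta
  keep <- meta$species == species & meta$compartment == compartment
  if (!any(keep)) stopf("no samples for %s/%s", species, compartment)
  sub <- subset_samples(es, keep)
  x <- if (sub$log2) sub$values else log2(sub$values + 1)
  ord <- sub$sample_meta %>%
    distinct(.data$stage, .data$stage_order) %>%
    arrange(.data$stage_order)
  profiles <- vapply(ord$stage, function(st) {
    rowMeans(x[, sub$sample_meta$stage == st, drop = FALSE])
  }, numeric(nrow(x)))
  list(profiles = profiles, stages = ord$stage)
}

#' Align developmental stages of two species by DTW
#'
#' Builds the cost matrix `1 - spearman(query stage i, reference stage
#' j)` over a shared ortholog index and warps the query stage series
#' onto the reference. Undefined correlations (constant profiles) get
#' the maximum cost 2. The best match of each query stage is the
#' reference stage with minimal pair cost among the optimal-path pairs
#' containing it; ties break toward the earlier reference stage.
#'
#' @param query,reference stage-series lists from [stage_series()],
#'   profiled over the identical ortholog-group index.
#' @return A `stage_warp` with an extra `best_match` tibble
#'   (`query_stage, reference_stage`) and stage labels on the path.
#' @export
align_stages <- function(query, reference) {
  if (!identical(rownames(query$profiles), rownames(reference$profiles))) {
    stopf("query and reference profiles must share the gene index")
  }
  m <- length(query$stages); n <- length(reference$stages)
  cost <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      r <- spearman_rho(query$profiles[, i], reference$profiles[, j])
      cost[i, j] <- if (is.na(r)) 2 else 1 - r
    }
  }
  w <- dtw_warp(cost)
  q_stages <- query$stages
  r_stages <- reference$stages
  w$path <- w$path %>%
    mutate(query_stage = q_stages[.data$query],
           reference_stage = r_stages[.data$reference])
  w$best_match <- w$path %>%
    group_by(.data$query) %>%
    arrange(.data$cost, .data$reference, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("query_stage", "reference_stage")
  w
}
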