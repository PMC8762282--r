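#' Filter genes by expression level
#'
#' Retains genes whose maximum FPKM across samples reaches `min_fpkm`,
#' the standard "expressed" filter applied per species before ortholog
#' integration. Gene order is preserved.
#'
#' @param es a [follicle_expr] object on the FPKM scale.
#' @param min_fpkm minimum FPKM (>= 0); default 1.
#' @return A filtered [follicle_expr]; warns (does not error) if no gene
#'   survives.
#' @export
filter_expressed <- function(es, min_fpkm = 1) {
  stopifnot(inherits(es, "follicle_expr"))
  if (min_fpkm < 0) stopf("min_fpkm must be >= 0")
  if (es$log2) stopf("filter_expressed expects FPKM-scale values")
  keep <- apply(es$values, 1, max) >= min_fpkm
  if (!any(keep)) warnf("no gene passes the FPKM >= %g filter", min_fpkm)
  follicle_expr(es$values[keep, , drop = FALSE], es$sample_meta)
}

#' Integrate per-species expression over one-to-one orthologs
#'
#' Re-indexes each species' matrix by ortholog group and binds the
#' sample columns of all species into one matrix. A group is kept only
#' if, in every species, its gene exists and passes the expression
#' filter in that species' own data — mirroring how a homologous
#' expressed-gene matrix is assembled from independent per-species
#' datasets.
#'
#' @param es_list named list of per-species [follicle_expr] objects
#'   (names are species codes).
#' @param orthologs long tibble `group_id, species, gene_id` with exactly
#'   one gene per species per group.
#' @param min_fpkm expression filter applied within each species.
#' @return A [follicle_expr] whose rows are ortholog group IDs and whose
#'   columns are the union of all samples.
#' @export
map_orthologs <- function(es_list, orthologs, min_fpkm = 1) {
  orthologs <- as_tibble(orthologs)
  sp_in_table <- unique(orthologs$species)
  missing_sp <- setdiff(names(es_list), sp_in_table)
  if (length(missing_sp) > 0) {
    stopf("species absent from ortholog table: %s",
          paste(missing_sp, collapse = ", "))
  }
  all_samples <- unlist(lapply(es_list, function(e) colnames(e$values)))
  if (anyDuplicated(all_samples) > 0) stopf("duplicate sample IDs")
  per_sp <- lapply(names(es_list), function(sp) {
    es <- filter_expressed(es_list[[sp]], min_fpkm)
    tab <- orthologs %>% filter(.data$species == sp)
    tab <- tab[tab$gene_id %in% rownames(es$values), ]
    m <- es$values[tab$gene_id, , drop = FALSE]
    rownames(m) <- tab$group_id
    m
  })
  keep <- Reduce(intersect, lapply(per_sp, rownames))
  keep <- unique(orthologs$group_id)[unique(orthologs$group_id) %in% keep]
  values <- do.call(cbind, lapply(per_sp, function(m)
    m[keep, , drop = FALSE]))
  meta <- bind_rows(lapply(es_list, function(e) e$sample_meta))
  follicle_expr(values, meta)
}

#' Remove batch effects by per-gene location-scale adjustment
#'
#' Works on the log2(FPKM + 1) scale: per gene and batch, the batch mean
#' is subtracted and the batch SD divided out, then the gene's pooled
#' mean and SD are restored, so gene-wise pooled moments are unchanged.
#' Population (1/n) SDs are used throughout, which makes the operation
#' exactly idempotent. A batch with zero SD for a gene gets the location
#' step only. This is a ComBat-like adjustment without empirical-Bayes
#' shrinkage.
#'
#' @param es a [follicle_expr] on the FPKM scale (log2-scale input is
#'   adjusted as-is).
#' @return A [follicle_expr] carrying log2-scale values (`log2 = TRUE`).
#' @export
remove_batch <- function(es) {
  stopifnot(inherits(es, "follicle_expr"))
  batch <- es$sample_meta$batch
  if (length(unique(batch)) < 2) stopf("need >= 2 batches")
  if (any(table(batch) < 2)) stopf("each batch needs >= 2 samples")
  x <- if (es$log2) es$values else log2(es$values + 1)
  adj <- x
  pooled_mean <- rowMeans(x)
  pooled_sd <- apply(x, 1, pop_sd)
  for (b in unique(batch)) {
    cols <- which(batch == b)
    bm <- rowMeans(x[, cols, drop = FALSE])
    bs <- apply(x[, cols, drop = FALSE], 1, pop_sd)
    centred <- x[, cols, drop = FALSE] - bm
    scale_ok <- bs > 1e-12 & pooled_sd > 1e-12
    fac <- ifelse(scale_ok, pooled_sd / pmax(bs, 1e-12), 1)
    adj[, cols] <- centred * fac + pooled_mean
  }
  follicle_expr(adj, es$sample_meta, log2 = TRUE)
}

#' Z-score matrix rows
#'
#' Each row is centred to mean 0 and scaled to population SD 1 (the
#' heatmap standardisation). Constant rows are emitted as all zeros with
#' a warning rather than NaN.
#'
#' @param mat numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  m <- rowMeans(mat)
  s <- apply(mat, 1, pop_sd)
  flat <- s < 1e-12
  if (any(flat)) warnf("%d constant row(s) emitted as zeros", sum(flat))
  s[flat] <- 1
  out <- (mat - m) / s
  out[flat, ] <- 0
  out
}

#' Hierarchically cluster samples on correlation distance
#'
#' Agglomerative clustering with average linkage on the distance
#' 1 - Pearson correlation between sample columns, cut into `k` groups.
#' `stats::hclust` resolves merge ties deterministically by the smaller
#' element index, so results are reproducible and invariant (as a
#' partition) to column permutation.
#'
#' @param mat numeric matrix, typically z-scored expression with samples
#'   in columns.
#' @param k number of clusters (>= 2, <= number of samples).
#' @return List with `labels` (named integer cluster ids) and `tree`
#'   (the `hclust` object).
#' @export
cluster_samples <- function(mat, k) {
  assert_count(k, "k", positive = TRUE)
  if (k < 2) stopf("k must be >= 2")
  if (k > ncol(mat)) stopf("k exceeds the number of samples")
  d <- as.dist(1 - cor(mat))
  tree <- hclust(d, method = "average")
  labels <- cutree(tree, k = k)
  list(labels = labels, tree = tree)
}

#' Name clusters from reference samples
#'
#' Each cluster is named by the majority stage-group of the reference
#' samples it contains; ties break toward the earlier developmental
#' group. Clusters without any reference sample are named "unassigned".
#'
#' @param labels named cluster labels from [cluster_samples()].
#' @param reference_groups named character vector mapping reference
#'   sample IDs to stage-group names.
#' @param group_order character vector giving the developmental order of
#'   group names (earliest first); defaults to order of appearance.
#' @return Tibble `cluster, name`.
#' @export
name_clusters <- function(labels, reference_groups, group_order = NULL) {
  if (is.null(group_order)) group_order <- unique(unname(reference_groups))
  tibble(cluster = sort(unique(unname(labels)))) %>%
    rowwise() %>%
    mutate(name = {
      members <- names(labels)[labels == .data$cluster]
      refs <- reference_groups[intersect(members, names(reference_groups))]
      if (length(refs) == 0) "unassigned" else {
        counts <- table(factor(refs, levels = group_order))
        names(counts)[which.max(counts)]  # which.max: first max = earliest
      }
    }) %>%
    ungroup()
}
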