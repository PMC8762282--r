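#' Per-gene negative-binomial Wald test
#'
#' Self-contained differential-expression test on FPKM-scale values:
#' a per-gene negative-binomial model with method-of-moments dispersion
#' (floored at 1e-8), a Wald test on the log2 fold change B vs A, and
#' Benjamini-Hochberg adjustment across tested genes. Dispersion is the
#' average of the two within-group moment estimates
#' `(var - mean) / mean^2`; the group-mean sampling variance is the
#' model-based `(mean + dispersion * mean^2) / n_reps`, propagated to
#' the log2 scale by the delta method.
#'
#' @param mat numeric matrix (genes x samples) of FPKM values.
#' @param cols_a,cols_b column indices (or names) of the two groups,
#'   each with >= 2 replicates.
#' @return Tibble `gene_id, mean_a, mean_b, log2fc, stat, p, padj` in
#'   input gene order. All-zero genes get `log2fc = 0, p = 1`.
#' @export
nb_wald_test <- function(mat, cols_a, cols_b) {
  a <- mat[, cols_a, drop = FALSE]
  b <- mat[, cols_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) stopf("need >= 2 replicates per group")
  eps <- 1e-8
  m_a <- unname(rowMeans(a)); m_b <- unname(rowMeans(b))
  v_a <- unname(apply(a, 1, var)); v_b <- unname(apply(b, 1, var))
  disp_term <- function(v, m) ifelse(m > 0, (v - m) / m^2, 0)
  disp <- pmax((disp_term(v_a, m_a) + disp_term(v_b, m_b)) / 2, eps)
  ma <- pmax(m_a, eps); mb <- pmax(m_b, eps)
  var_mean_a <- (ma + disp * ma^2) / ncol(a)
  var_mean_b <- (mb + disp * mb^2) / ncol(b)
  se_lfc <- sqrt(var_mean_a / ma^2 + var_mean_b / mb^2) / log(2)
  lfc <- log2(mb / ma)
  stat <- ifelse(se_lfc > 0, lfc / se_lfc, 0)
  p <- 2 * pnorm(-abs(stat))
  dead <- m_a == 0 & m_b == 0
  lfc[dead] <- 0; stat[dead] <- 0; p[dead] <- 1
  tibble(gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
         mean_a = m_a, mean_b = m_b, log2fc = lfc, stat = stat, p = p,
         padj = p.adjust(p, method = "BH"))
}

#' Stage-marker gene sets for one species and compartment
#'
#' Calls the genes differentially highly expressed at each developmental
#' stage (one-vs-rest [nb_wald_test()] against all other stages pooled):
#' a gene is a marker of stage S if its fold change is positive, its BH
#' adjusted p-value passes `alpha`, and its mean FPKM within S reaches
#' `min_fpkm`. Stages with a single replicate are excluded with a
#' warning.
#'
#' @param es a [follicle_expr] on the FPKM scale.
#' @param species,compartment which samples to analyse.
#' @param min_fpkm stage-mean expression floor (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return Tibble `stage, gene_id, log2fc, padj, mean_fpkm`, one row per
#'   marker gene per stage.
#' @export
stage_markers <- function(es, species, compartment, min_fpkm = 1,
                          alpha = 0.05) {
  meta <- es$sample_meta
  keep <- meta$species == species & meta$compartment == compartment
  if (!any(keep)) stopf("no samples for %s/%s", species, compartment)
  sub <- subset_samples(es, keep)
  stages <- sub$sample_meta %>%
    count(.data$stage, .data$stage_order) %>%
    arrange(.data$stage_order)
  usable <- stages$n >= 2
  if (any(!usable)) {
    warnf("excluding single-replicate stage(s): %s",
          paste(stages$stage[!usable], collapse = ", "))
    stages <- stages[usable, ]
  }
  if (nrow(stages) < 2) stopf("need >= 2 stages with replicates")
  purrr::map_dfr(stages$stage, function(st) {
    in_stage <- sub$sample_meta$stage == st
    rest <- sub$sample_meta$stage %in% stages$stage & !in_stage
    de <- nb_wald_test(sub$values, which(rest), which(in_stage))
    de %>%
      mutate(stage = st, mean_fpkm = .data$mean_b) %>%
      filter(.data$log2fc > 0, .data$padj <= alpha,
             .data$mean_fpkm >= min_fpkm) %>%
      select("stage", "gene_id", "log2fc", "padj", "mean_fpkm")
  })
}
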