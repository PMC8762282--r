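test_that("nb_wald_test behaves on null, planted, and degenerate genes", {
  set.seed(61)
  m <- matrix(rlnorm(100 * 6, 3, 0.3), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  # identical groups: zero fold change, high p
  de0 <- nb_wald_test(cbind(m[, 1:3], m[, 1:3]), 1:3, 4:6)
  expect_true(all(de0$log2fc == 0))
  expect_true(all(de0$p >= 0.5))
  # all-zero gene
  mz <- rbind(m, zero = 0)
  dez <- nb_wald_test(mz, 1:3, 4:6)
  expect_equal(dez$p[dez$gene_id == "zero"], 1)
  expect_equal(dez$log2fc[dez$gene_id == "zero"], 0)
  expect_error(nb_wald_test(m, 1, 2:3), "replicates")
})

test_that("BH adjustment matches the closed-form step-up", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.03))
  set.seed(67)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("planted 16-fold genes are detected at the stated power", {
  g <- generate_expression(n_genes = 500, n_reps = 3, effect_fold = 16,
                           n_specific = 40, seed = 71)
  es <- g$esets$gal
  meta <- es$sample_meta
  rest <- which(meta$compartment == "GC" & meta$stage != "s2")
  s2 <- which(meta$compartment == "GC" & meta$stage == "s2")
  de <- nb_wald_test(es$values, rest, s2)
  hits <- de$gene_id[de$padj <= 0.05 & de$log2fc > 0]
  expect_gte(sum(g$truth$planted_specific_genes %in% hits), 34)
})

test_that("stage_markers assigns genes to the right stages", {
  g <- generate_expression(n_genes = 200, n_reps = 3, seed = 73,
                           markers_per_stage = 15, n_specific = 0)
  mk <- stage_markers(g$esets$gal, "gal", "GC")
  for (r in 1:3) {
    planted <- paste("gal", g$truth$marker_blocks[[paste0("GC.", r)]],
                     sep = "_")
    called <- mk$gene_id[mk$stage == paste0("s", r)]
    jac <- length(intersect(planted, called)) /
      length(union(planted, called))
    expect_gte(jac, 0.85)
  }
  # flat genes belong to no stage set
  flat <- setdiff(rownames(g$esets$gal$values),
                  paste("gal", unlist(g$truth$marker_blocks), sep = "_"))
  expect_lte(mean(flat %in% mk$gene_id), 0.05)
})

test_that("stage_markers excludes single-replicate stages with a warning", {
  g <- generate_expression(n_genes = 50, n_reps = 2, seed = 79,
                           markers_per_stage = 5, n_specific = 0)
  es <- g$esets$gal
  keep <- !(es$sample_meta$stage == "s3" & es$sample_meta$replicate == 2 &
              es$sample_meta$compartment == "GC")
  es2 <- follicle_expr(es$values[, keep], es$sample_meta[keep, ])
  expect_warning(mk <- stage_markers(es2, "gal", "GC"), "single-replicate")
  expect_false("s3" %in% mk$stage)
})

test_that("homology_overlap computes intersection over union", {
  orth <- tibble::tibble(
    group_id = rep(c("o1", "o2", "o3"), each = 3),
    species = rep(c("gal", "hsa", "bta"), 3),
    gene_id = paste(rep(c("gal", "hsa", "bta"), 3),
                    rep(c("o1", "o2", "o3"), each = 3), sep = "_"))
  sets <- list(gal = c("gal_o1", "gal_o2"), hsa = "hsa_o1",
               bta = c("bta_o1", "bta_o3"))
  expect_equal(homology_overlap(sets, orth), 100 / 3, tolerance = 1e-12)
  disjoint <- list(gal = "gal_o1", hsa = "hsa_o2")
  expect_equal(homology_overlap(disjoint, orth), 0)
  same <- list(gal = c("gal_o1", "gal_o2"), hsa = c("hsa_o1", "hsa_o2"))
  expect_equal(homology_overlap(same, orth), 100)
  empty <- list(gal = character(), hsa = character())
  expect_true(is.na(homology_overlap(empty, orth)))
})

test_that("ectopic_genes follows the compartment-switch rule", {
  orth <- tibble::tibble(
    group_id = rep(c("o1", "o2", "o3"), each = 2),
    species = rep(c("gal", "hsa"), 3),
    gene_id = paste(rep(c("gal", "hsa"), 3),
                    rep(c("o1", "o2", "o3"), each = 2), sep = "_"))
  sets <- list(
    gal = list(GC = c("gal_o2", "gal_o3"), TC = c("gal_o1", "gal_o3")),
    hsa = list(GC = c("hsa_o1", "hsa_o2"), TC = character()))
  out <- ectopic_genes(sets, orth, query = "gal")
  # o1: TC-only in chicken, GC-only in human -> ectopic
  expect_identical(out$group_id, "o1")
  # o2 GC-only in both -> not ectopic; o3 both compartments -> excluded
  expect_false(any(c("o2", "o3") %in% out$group_id))
})

test_that("hypergeom_tail is exact on small closed-form cases", {
  expect_equal(hypergeom_tail(10, 5, 4, 3), 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(20, 5, 5, 4), 76 / 15504, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 5, 4, 0), 1)
  expect_error(hypergeom_tail(10, 11, 4, 0), "inconsistent")
  expect_error(hypergeom_tail(10, 5, 4, 5), "inconsistent")
})

test_that("go_enrich ranks a fully recovered term first and controls FDR", {
  background <- paste0("g", 1:200)
  set.seed(82)
  ann <- tibble::tibble(
    term = rep(paste0("T", 1:10), each = 12),
    gene = c(paste0("g", 1:12),
             replicate(9, sample(background, 12)) |> as.vector()))
  res <- go_enrich(paste0("g", 1:12), ann, background)
  expect_identical(res$term[1], "T1")
  expect_equal(res$overlap[1], 12L)
  # random queries under the null rarely reach significance
  set.seed(83)
  n_sig <- vapply(1:30, function(i) {
    q <- sample(background, 15)
    sum(go_enrich(q, ann, background)$padj <= 0.05)
  }, numeric(1))
  expect_lte(mean(n_sig > 0), 0.15)
  expect_error(go_enrich("not_there", ann, background), "subset")
})

test_that("species_specific_bps isolates target-only terms", {
  e <- function(terms, padj) tibble::tibble(term = terms, padj = padj)
  enr <- list(
    gal = e(paste0("T", 1:40), c(rep(0.01, 40))),
    hsa = e(paste0("T", 1:40), c(rep(0.9, 10), rep(0.01, 30))),
    bta = e(paste0("T", 1:40), c(rep(0.9, 10), rep(0.01, 30))))
  out <- species_specific_bps(enr, "gal")
  expect_setequal(out$specific, paste0("T", 1:10))
  expect_equal(out$percent, 25)
  none <- species_specific_bps(list(gal = e("T1", 0.9),
                                    hsa = e("T1", 0.9)), "gal")
  expect_identical(none$specific, character())
  expect_true(is.na(none$percent))
})

test_that("bp_overlap_test matches the combinatorial oracle", {
  expect_equal(bp_overlap_test(paste0("t", 1:3), paste0("t", 4:6),
                               paste0("t", 1:10)), 1)
  expect_equal(bp_overlap_test(character(), paste0("t", 1:3),
                               paste0("t", 1:10)), 1)
  # N=50, K=10, n=8, k=5 exact sum vs enumeration-based formula
  universe <- paste0("u", 1:50)
  other <- paste0("u", 1:10)
  candidate <- c(paste0("u", 1:5), paste0("u", 21:23))
  got <- bp_overlap_test(candidate, other, universe)
  want <- sum(vapply(5:8, function(k)
    choose(10, k) * choose(40, 8 - k) / choose(50, 8), numeric(1)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("extract_spgs excludes candidates present in the other compartment", {
  target_enrich <- tibble::tibble(term = c("A", "B"), padj = c(1e-6, 1e-5))
  other_enrich <- tibble::tibble(term = "B", padj = 0.001)
  ann <- tibble::tibble(term = c("A", "A", "A", "B"),
                        gene = c("g1", "g2", "g3", "g9"))
  t_sets <- tibble::tibble(stage = "s2", gene_id = c("g1", "g2", "g9"))
  o_sets <- tibble::tibble(stage = "s2", gene_id = "g2")
  out <- extract_spgs(target_enrich, other_enrich, ann, t_sets, o_sets,
                      top_k = 10)
  expect_identical(out$kept_terms, "A")        # B present in other comp.
  expect_identical(out$candidates, c("g1", "g2", "g3"))
  # g2 in the other compartment's sets -> excluded; g3 not in target sets
  expect_identical(out$spgs, "g1")
})

test_that("pipeline-scale specific-gene recovery hits the planted truth", {
  dir <- fixture_dir()
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$dir <- dir
  report <- run_pipeline(cfg, report_path = tempfile(fileext = ".json"))
  expect_gte(report$specific$spg_precision, 0.85)
  expect_gte(report$specific$spg_recall, 0.85)
  expect_true(report$specific$tc_gene_excluded)
})
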