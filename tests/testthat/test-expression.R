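test_that("filter_expressed keeps genes by their maximum FPKM", {
  m <- named_matrix(c(0.5, 0.2,
                      1.0, 0.0,
                      0.9, 0.9,
                      2.0, 0.1), paste0("g", 1:4), c("a", "b"))
  es <- toy_eset(m)
  out <- filter_expressed(es, 1)
  expect_identical(rownames(out$values), c("g2", "g4"))
  expect_warning(filter_expressed(es, 100), "no gene")
})

test_that("map_orthologs integrates and drops incomplete groups", {
  orth <- tibble::tibble(
    group_id = rep(c("og1", "og2"), each = 2),
    species = rep(c("gal", "hsa"), 2),
    gene_id = c("gal_a", "hsa_a", "gal_b", "hsa_b"))
  gal <- toy_eset(named_matrix(c(5, 5, 2, 2), c("gal_a", "gal_b"),
                               c("g1", "g2")), species = "gal")
  hsa <- toy_eset(named_matrix(c(3, 3, 0.2, 0.3), c("hsa_a", "hsa_b"),
                               c("h1", "h2")), species = "hsa")
  out <- map_orthologs(list(gal = gal, hsa = hsa), orth, min_fpkm = 1)
  # og2 fails the filter in human and is dropped
  expect_identical(rownames(out$values), "og1")
  expect_identical(colnames(out$values), c("g1", "g2", "h1", "h2"))
  # a group whose gene is absent in one species is dropped too
  hsa2 <- toy_eset(named_matrix(c(3, 3), "hsa_a", c("h1", "h2")),
                   species = "hsa")
  out2 <- map_orthologs(list(gal = gal, hsa = hsa2), orth)
  expect_identical(rownames(out2$values), "og1")
  # duplicate sample ids error
  gal_dup <- toy_eset(named_matrix(c(5, 5), "gal_a", c("h1", "x")),
                      species = "gal")
  expect_error(map_orthologs(list(gal = gal_dup, hsa = hsa), orth),
               "duplicate")
})

test_that("filter-then-map commutes with map-then-filter on 1:1 tables", {
  g <- generate_expression(n_genes = 80, n_reps = 2, seed = 31,
                           markers_per_stage = 6, n_specific = 5)
  a <- map_orthologs(g$esets, g$orthologs, min_fpkm = 1)
  b_in <- lapply(g$esets, filter_expressed, min_fpkm = 1)
  b <- map_orthologs(b_in, g$orthologs, min_fpkm = 1)
  expect_equal(a$values, b$values)
})

test_that("remove_batch erases additive offsets and preserves moments", {
  set.seed(41)
  base <- matrix(rnorm(50 * 8, 6, 1), 50, 8,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  fpkm <- 2^base - 1
  fpkm_shift <- fpkm
  # batch B = samples 5..8, offset +2 on log2(FPKM+1)
  fpkm_shift[, 5:8] <- 2^(base[, 5:8] + 2) - 1
  es <- toy_eset(pmax(fpkm_shift, 0), batch = rep(c("A", "B"), each = 4))
  es$sample_meta$batch <- rep(c("A", "B"), each = 4)
  out <- remove_batch(es)
  for (g in 1:50) {
    expect_equal(mean(out$values[g, 1:4]), mean(out$values[g, 5:8]),
                 tolerance = 1e-9)
  }
  # gene-wise pooled means on the working scale are preserved
  logx <- log2(es$values + 1)
  expect_equal(rowMeans(out$values), rowMeans(logx), tolerance = 1e-9)
  # idempotence
  again <- remove_batch(out)
  expect_equal(again$values, out$values, tolerance = 1e-9)
})

test_that("remove_batch leaves batch-free data essentially unchanged", {
  # every gene is a stage marker with modest replicate noise, so
  # per-gene variance is dominated by shared structure and the
  # per-batch moments are well determined
  g <- generate_expression(n_genes = 120, n_reps = 6, batch_sd = 0,
                           gene_sd = 0.1, seed = 13,
                           markers_per_stage = 20, n_specific = 0)
  es <- map_orthologs(g$esets, g$orthologs)
  out <- remove_batch(es)
  logx <- log2(es$values + 1)
  cors <- vapply(seq_len(nrow(logx)), function(i)
    cor(logx[i, ], out$values[i, ]), numeric(1))
  expect_true(all(cors >= 0.999))
})

test_that("remove_batch shrinks between-batch variance of null genes", {
  g <- generate_expression(n_genes = 150, n_reps = 3, batch_sd = 2,
                           effect_fold = 1, n_specific = 0,
                           markers_per_stage = 0, seed = 17)
  es <- map_orthologs(g$esets, g$orthologs, min_fpkm = 0)
  out <- remove_batch(es)
  batch <- es$sample_meta$batch
  between_var <- function(m) {
    vapply(seq_len(nrow(m)), function(i) {
      var(tapply(m[i, ], batch, mean))
    }, numeric(1))
  }
  before <- between_var(log2(es$values + 1))
  after <- between_var(out$values)
  expect_gte(median(before) / median(after), 10)
})

test_that("zscore_rows standardises with population SD", {
  out <- zscore_rows(matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(out), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-4)
  expect_warning(flat <- zscore_rows(matrix(c(5, 5, 5), 1)), "constant")
  expect_identical(as.numeric(flat), c(0, 0, 0))
  set.seed(1)
  m <- matrix(rnorm(60), 6)
  z <- zscore_rows(m)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, function(x)
    sqrt(mean((x - mean(x))^2))) - 1) < 1e-12))
})

test_that("cluster_samples matches a brute-force average-linkage oracle", {
  set.seed(23)
  m <- matrix(rnorm(240), 40, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  cl <- cluster_samples(m, 2)
  d <- 1 - cor(m)
  expect_equal(sort(cl$tree$height),
               sort(brute_average_linkage_heights(as.dist(d))),
               tolerance = 1e-12)
  # identical columns merge first
  m2 <- cbind(m, s7 = m[, 6])
  cl2 <- cluster_samples(m2, 2)
  first <- sort(abs(cl2$tree$merge[1, ]))
  expect_equal(first, c(6, 7))
  # correlated pair forms one cluster at k = 2
  base <- rnorm(30)
  m3 <- cbind(a = base + rnorm(30, 0, 0.05), b = base + rnorm(30, 0, 0.05),
              c = rnorm(30))
  cl3 <- cluster_samples(m3, 2)
  expect_identical(cl3$labels[["a"]], cl3$labels[["b"]])
  expect_false(cl3$labels[["a"]] == cl3$labels[["c"]])
  expect_error(cluster_samples(m, 7), "exceeds")
})

test_that("clustering partition is invariant to column permutation", {
  set.seed(29)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  cl <- cluster_samples(m, 3)
  perm <- sample(10)
  cl_p <- cluster_samples(m[, perm], 3)
  # same partition: co-membership matrices agree
  co <- function(lab, ids) outer(lab[ids], lab[ids], "==")
  ids <- paste0("s", 1:10)
  expect_equal(co(cl$labels, ids), co(cl_p$labels, ids))
})

test_that("name_clusters uses reference majority with earliest-stage ties", {
  labels <- c(HG_antral1 = 1, HG_antral2 = 1, GAL_F1 = 1, HG_pre1 = 2,
              lonely = 3)
  refs <- c(HG_antral1 = "antral follicles", HG_antral2 = "antral follicles",
            HG_pre1 = "preantral follicles")
  out <- name_clusters(labels, refs,
                       group_order = c("preantral follicles",
                                       "antral follicles"))
  expect_identical(out$name, c("antral follicles", "preantral follicles",
                               "unassigned"))
  # all-distinct tie resolves to the earliest developmental group
  labels2 <- c(a = 1, b = 1)
  refs2 <- c(a = "antral follicles", b = "preantral follicles")
  out2 <- name_clusters(labels2, refs2,
                        group_order = c("preantral follicles",
                                        "antral follicles"))
  expect_identical(out2$name, "preantral follicles")
})
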