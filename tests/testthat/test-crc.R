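test_that("scan_motifs matches exhaustive window scoring", {
  p <- consensus_pwm("M1", "TFX", "ACGT")
  hit <- scan_motifs(paste0("TTTT", "ACGT", "TTTT"), p, 0.8)
  expect_gte(nrow(hit), 1)
  expect_true(any(hit$start == 5 & hit$strand == "+"))

  expect_equal(nrow(scan_motifs(strrep("N", 30), p, 0.5)), 0)
  expect_equal(nrow(scan_motifs("AC", p, 0.8)), 0)

  set.seed(113)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    thr <- sample(c(0.5, 0.7, 0.9), 1)
    got <- scan_motifs(s, p, thr)
    want <- brute_scan(s, p, thr)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      fw <- sort(vapply(want[vapply(want, function(h) h["strand"] == 1,
                                    logical(1))], function(h)
        unname(h["start"]), numeric(1)))
      expect_equal(sort(got$start[got$strand == "+"]), fw)
    }
  }
})

test_that("reverse-strand hits are reported on the forward frame", {
  p <- consensus_pwm("M1", "TFX", "ACCGGT")
  rc <- "ACCGGT"  # self-reverse-complement? no: revcomp(ACCGGT)=ACCGGT
  s <- paste0("TTTTT", "ACCGGT", "TTTTT")
  hits <- scan_motifs(s, p, 0.9)
  expect_true(all(hits$start == 6 & hits$end == 11))
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("build_tf_network recovers exactly the planted edge set", {
  ep <- generate_epigenome(n_enh = 60, n_se = 8, seed = 127)
  tfs <- ep$truth$tf_genes
  tf_constituents <- purrr::imap_dfr(
    ep$truth$se_constituents[tfs],
    function(pks, tf) tibble::tibble(tf = tf, peak_id = pks))
  net <- build_tf_network(ep$sequences, tf_constituents, ep$pwms)
  planted <- ep$truth$planted_network$edges
  planted <- planted[planted$to %in% tfs, ]
  got <- dplyr::arrange(net$edges, from, to)
  want <- dplyr::arrange(planted, from, to)
  expect_equal(as.data.frame(got), as.data.frame(want))
  # no motifs planted -> empty edges
  net0 <- build_tf_network(
    setNames(vapply(seq_along(ep$sequences),
                    function(i) strrep("T", 100), character(1)),
             names(ep$sequences)),
    tf_constituents, ep$pwms)
  expect_equal(nrow(net0$edges), 0)
})

test_that("closeness matches hand-computed and Floyd-Warshall oracles", {
  star <- list(nodes = c("A", "B", "C"),
               edges = tibble::tibble(from = c("A", "A"),
                                      to = c("B", "C")))
  oc <- closeness_centrality(star, "out")
  expect_equal(unname(oc), c(1, 0, 0))
  ic <- closeness_centrality(star, "in")
  expect_equal(unname(ic), c(0, 0.5, 0.5))

  cyc <- list(nodes = c("A", "B", "C"),
              edges = tibble::tibble(from = c("A", "B", "C"),
                                     to = c("B", "C", "A")))
  expect_equal(unname(closeness_centrality(cyc, "out")),
               rep(0.75, 3))

  edgeless <- list(nodes = c("A", "B"),
                   edges = tibble::tibble(from = character(),
                                          to = character()))
  expect_equal(unname(closeness_centrality(edgeless, "out")), c(0, 0))

  set.seed(131)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    adj <- matrix(rbinom(n * n, 1, 0.4), n)
    diag(adj) <- 0
    nodes <- paste0("v", seq_len(n))
    idx <- which(adj > 0, arr.ind = TRUE)
    net <- list(nodes = nodes,
                edges = tibble::tibble(from = nodes[idx[, 1]],
                                       to = nodes[idx[, 2]]))
    expect_equal(unname(closeness_centrality(net, "out")),
                 fw_closeness(adj, "out"), tolerance = 1e-12)
    expect_equal(unname(closeness_centrality(net, "in")),
                 fw_closeness(adj, "in"), tolerance = 1e-12)
    # igraph cross-check
    if (nrow(net$edges) > 0) {
      g <- igraph::graph_from_data_frame(net$edges, vertices = nodes)
      hc <- igraph::harmonic_centrality(g, mode = "out",
                                        normalized = TRUE)
      expect_equal(unname(closeness_centrality(net, "out")),
                   unname(hc[nodes]), tolerance = 1e-12)
    }
  }
})

test_that("adding an edge never decreases out-closeness", {
  set.seed(137)
  for (i in 1:15) {
    n <- 6
    adj <- matrix(rbinom(n * n, 1, 0.3), n)
    diag(adj) <- 0
    zero <- which(adj == 0 & diag(n) == 0, arr.ind = TRUE)
    if (nrow(zero) == 0) next
    add <- zero[sample(nrow(zero), 1), ]
    before <- fw_closeness(adj, "out")
    nodes <- paste0("v", 1:n)
    to_net <- function(a) {
      idx <- which(a > 0, arr.ind = TRUE)
      list(nodes = nodes, edges = tibble::tibble(from = nodes[idx[, 1]],
                                                 to = nodes[idx[, 2]]))
    }
    s1 <- closeness_centrality(to_net(adj), "out")
    adj[add[1], add[2]] <- 1
    s2 <- closeness_centrality(to_net(adj), "out")
    expect_true(all(s2 - s1 >= -1e-12))
  }
})

test_that("hub_tfs thresholds at mean plus one population SD", {
  scores <- c(a = 1, b = 1, c = 1, d = 5)
  expect_identical(hub_tfs(scores), "d")  # threshold 2 + sqrt(3)
  expect_identical(hub_tfs(c(a = 2, b = 2, c = 2)), character())
})

test_that("find_circuits returns maximal directed cliques exactly", {
  mk <- function(from, to, nodes) {
    list(nodes = nodes, edges = tibble::tibble(from = from, to = to))
  }
  pair <- mk(c("A", "B"), c("B", "A"), c("A", "B", "C"))
  expect_equal(find_circuits(pair), list(c("A", "B")))
  one_way <- mk("A", "B", c("A", "B"))
  expect_equal(find_circuits(one_way), list())

  # planted 3-clique plus distractor edges, checked against an
  # exhaustive subset enumeration
  set.seed(139)
  nodes <- paste0("v", 1:8)
  cl <- c("v1", "v2", "v3")
  edges <- expand.grid(from = cl, to = cl, stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, ]
  extra <- tibble::tibble(from = c("v4", "v5", "v6", "v4"),
                          to = c("v5", "v6", "v4", "v1"))
  net <- list(nodes = nodes,
              edges = dplyr::bind_rows(tibble::as_tibble(edges), extra))
  got <- find_circuits(net)
  # oracle: all subsets of size >= 2 that are directed cliques, maximal
  has_edge <- function(a, b) any(net$edges$from == a & net$edges$to == b)
  is_clique <- function(s) {
    all(vapply(s, function(a) all(vapply(setdiff(s, a), function(b)
      has_edge(a, b) && has_edge(b, a), logical(1))), logical(1)))
  }
  subsets <- unlist(lapply(2:length(nodes), function(k)
    utils::combn(nodes, k, simplify = FALSE)), recursive = FALSE)
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(s) !any(vapply(cliques, function(t)
    length(t) > length(s) && all(s %in% t), logical(1))), cliques)
  expect_equal(lapply(got, sort), lapply(maximal, sort))
})

test_that("every circuit member has in/out degree within the circuit", {
  ep <- generate_epigenome(n_enh = 40, n_se = 6, seed = 149)
  tfs <- ep$truth$tf_genes
  tf_constituents <- purrr::imap_dfr(
    ep$truth$se_constituents[tfs],
    function(pks, tf) tibble::tibble(tf = tf, peak_id = pks))
  crc <- crc_analysis(ep$sequences, tf_constituents, ep$pwms)
  for (circ in crc$circuits) {
    for (v in circ) {
      expect_true(any(crc$edges$from == v & crc$edges$to %in%
                        setdiff(circ, v)))
      expect_true(any(crc$edges$to == v & crc$edges$from %in%
                        setdiff(circ, v)))
    }
  }
  # the planted hub is strictly maximal and flagged
  oc <- setNames(crc$closeness$closeness_out, crc$closeness$tf)
  hub <- ep$truth$planted_network$hub
  expect_true(all(oc[hub] > oc[setdiff(names(oc), hub)]))
  expect_true(hub %in% crc$closeness$tf[crc$closeness$hub])
  expect_true(any(vapply(crc$circuits, function(s)
    setequal(s, ep$truth$planted_network$circuit), logical(1))))
})
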