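# Independent oracles used across tests. Each one deliberately takes a
# different computational route than the package implementation.

# exhaustive enumeration of all monotone warping paths through a cost
# matrix under steps (1,1), (1,0), (0,1) with full boundary constraints
brute_dtw_cost <- function(cost) {
  m <- nrow(cost); n <- ncol(cost)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(cost[1, 1])
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    cost[i, j] + best
  }
  rec(m, n)
}

# upper-tail hypergeometric probability by enumerating every n-subset of
# an N-element population whose first K elements are the successes
enum_hypergeom_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

# closed-form BH step-up from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# all-pairs shortest paths by Floyd-Warshall over an adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# harmonic out/in closeness from a Floyd-Warshall distance matrix
fw_closeness <- function(adj, direction = "out") {
  d <- floyd_warshall(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    dv <- if (direction == "out") d[v, -v] else d[-v, v]
    sum(1 / dv[is.finite(dv) & dv > 0]) / (n - 1)
  }, numeric(1))
}

# naive GSEA running sum, plain loop; magnitude ties prefer the
# positive extremum (the documented convention)
naive_gsea_es <- function(genes, scores, set, weight = 1) {
  N <- length(genes)
  hit <- genes %in% set
  Nh <- sum(hit)
  wsum <- sum(abs(scores[hit])^weight)
  run <- 0
  pos <- -Inf; neg <- Inf
  for (i in seq_len(N)) {
    if (hit[i]) run <- run + abs(scores[i])^weight / wsum
    else run <- run - 1 / (N - Nh)
    if (run > pos) pos <- run
    if (run < neg) neg <- run
  }
  if (pos >= -neg - 1e-12) pos else neg
}

# brute-force average-linkage merge heights on a distance matrix
brute_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          dij <- mean(d[clusters[[i]], clusters[[j]]])
          if (dij < best_d) { best_d <- dij; best <- c(i, j) }
        }
      }
    }
    heights[step] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# base-by-base background-subtracted area over a region
per_base_signal <- function(start, end, track, control = NULL) {
  val_at <- function(track, pos) {
    hit <- track$start <= pos & track$end > pos
    if (any(hit)) track$value[hit][1] else 0
  }
  total <- 0
  for (pos in seq(start, end - 1)) {
    v <- val_at(track, pos)
    if (!is.null(control)) v <- v - val_at(control, pos)
    total <- total + v
  }
  max(total, 0)
}

# exhaustive PWM window scoring on both strands
brute_scan <- function(sequence, pwm, threshold) {
  lo <- log2(pmax(pwm$mat, 1e-6) / pwm$background[rownames(pwm$mat)])
  L <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  score_window <- function(s) {
    b <- strsplit(s, "")[[1]]
    tot <- 0
    for (j in seq_len(L)) {
      if (!b[j] %in% rownames(lo)) return(-Inf)
      tot <- tot + lo[b[j], j]
    }
    tot
  }
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  hits <- list()
  W <- nchar(sequence)
  for (i in seq_len(max(W - L + 1, 0))) {
    win <- substr(sequence, i, i + L - 1)
    if (score_window(win) >= threshold * max_score) {
      hits[[length(hits) + 1]] <- c(start = i, strand = 1)
    }
    if (score_window(revcomp(win)) >= threshold * max_score) {
      hits[[length(hits) + 1]] <- c(start = i, strand = -1)
    }
  }
  hits
}
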