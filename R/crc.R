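#' Build the super-enhancer-based TF regulatory network
#'
#' Directed graph over candidate transcription factors: an edge A -> B
#' exists when at least one motif hit of A's PWM occurs in any
#' super-enhancer constituent sequence assigned to B. Candidate TFs are
#' those with at least one PWM and at least one assigned SE constituent;
#' TFs without an SE assignment are excluded from the node set.
#' Self-edges are recorded but ignored by the centrality and circuit
#' computations.
#'
#' @param sequences named character vector of constituent DNA sequences
#'   (names are peak/constituent IDs).
#' @param tf_constituents tibble `tf, peak_id` mapping each candidate TF
#'   to the constituent peaks of its super-enhancer(s).
#' @param pwms named list of `pwm` objects; each candidate TF needs one
#'   (list names or `$tf` fields are matched against TF names).
#' @param threshold motif-scan threshold (fraction of max score).
#' @return A `tf_network` object: list with `nodes` (character),
#'   `edges` (tibble `from, to`), and the call parameters.
#' @export
build_tf_network <- function(sequences, tf_constituents, pwms,
                             threshold = 0.8) {
  tf_constituents <- as_tibble(tf_constituents)
  pwm_tf <- vapply(pwms, function(p) p$tf, character(1))
  nodes <- sort(unique(tf_constituents$tf))
  no_pwm <- setdiff(nodes, pwm_tf)
  if (length(no_pwm) > 0) {
    stopf("candidate TF(s) without a PWM: %s", paste(no_pwm, collapse = ", "))
  }
  missing_seq <- setdiff(tf_constituents$peak_id, names(sequences))
  if (length(missing_seq) > 0) {
    stopf("missing constituent sequence(s): %s",
          paste(head(missing_seq, 3), collapse = ", "))
  }
  edges <- list()
  for (a in nodes) {
    pwm <- pwms[[which(pwm_tf == a)[1]]]
    for (b in nodes) {
      pks <- tf_constituents$peak_id[tf_constituents$tf == b]
      hit <- FALSE
      for (pk in pks) {
        if (nrow(scan_motifs(sequences[[pk]], pwm, threshold)) > 0) {
          hit <- TRUE
          break
        }
      }
      if (hit) edges[[length(edges) + 1]] <- tibble(from = a, to = b)
    }
  }
  edges <- if (length(edges) > 0) bind_rows(edges) else
    tibble(from = character(), to = character())
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("<tf_network> %d TFs, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Harmonic closeness centrality of network nodes
#'
#' `score(v) = sum over u != v of 1 / d(v, u), divided by (n - 1)`, with
#' unreachable nodes contributing 0 — well defined on disconnected
#' directed graphs. Direction `"out"` follows edges from v (external
#' regulatory capacity); `"in"` follows edges into v (being regulated).
#' Self-edges are ignored.
#'
#' @param network a `tf_network`, or a list with `nodes` and `edges`.
#' @param direction `"out"` or `"in"`.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
closeness_centrality <- function(network, direction = c("out", "in")) {
  direction <- match.arg(direction)
  nodes <- network$nodes
  n <- length(nodes)
  if (n < 2) stopf("need >= 2 nodes")
  edges <- network$edges %>% filter(.data$from != .data$to)
  adj <- if (direction == "out") {
    split(match(edges$to, nodes), factor(edges$from, levels = nodes))
  } else {
    split(match(edges$from, nodes), factor(edges$to, levels = nodes))
  }
  scores <- vapply(seq_len(n), function(v) {
    # BFS from v
    dist <- rep(NA_integer_, n)
    dist[v] <- 0L
    frontier <- v
    d <- 0L
    while (length(frontier) > 0) {
      d <- d + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!is.na(nxt)]
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    sum(1 / dist[-v], na.rm = TRUE) / (n - 1)
  }, numeric(1))
  setNames(scores, nodes)
}

#' Flag hub transcription factors
#'
#' Hubs are nodes whose out-closeness exceeds the mean plus
#' `multiplier` population SDs of all node scores. With zero variance
#' no node is a hub.
#'
#' @param scores named numeric vector (out-closeness).
#' @param multiplier SD multiplier (default 1).
#' @return Character vector of hub TF names.
#' @export
hub_tfs <- function(scores, multiplier = 1) {
  if (length(scores) < 2) stopf("need >= 2 nodes")
  s <- pop_sd(scores)
  if (s < 1e-15) return(character())
  names(scores)[scores > mean(scores) + multiplier * s]
}

#' Find transcriptional regulatory circuits
#'
#' Circuits are maximal node sets of size >= 2 in which every ordered
#' pair is connected by an edge — fully interconnected directed cliques,
#' i.e. maximal cliques of the mutual-edge graph. Reported sorted by
#' size descending.
#'
#' @param network a `tf_network`.
#' @return List of character vectors (sorted members).
#' @export
find_circuits <- function(network) {
  edges <- network$edges %>% filter(.data$from != .data$to)
  if (nrow(edges) == 0) return(list())
  key <- paste(edges$from, edges$to, sep = "\r")
  rev_key <- paste(edges$to, edges$from, sep = "\r")
  mutual <- edges[key %in% rev_key, ]
  if (nrow(mutual) == 0) return(list())
  g <- igraph::graph_from_data_frame(mutual, directed = FALSE,
                                     vertices = network$nodes)
  g <- igraph::simplify(g)
  cl <- igraph::max_cliques(g, min = 2)
  cl <- lapply(cl, function(v) sort(names(v)))
  cl[order(-vapply(cl, length, integer(1)),
           vapply(cl, function(v) v[1], character(1)))]
}

#' Full core-regulatory-circuitry analysis
#'
#' Convenience wrapper: builds the network, computes both closeness
#' directions, flags hubs, and extracts circuits.
#'
#' @inheritParams build_tf_network
#' @param hub_multiplier SD multiplier for [hub_tfs()].
#' @return The `tf_network` with `closeness` (tibble
#'   `tf, closeness_out, closeness_in, hub`) and `circuits` attached.
#' @export
crc_analysis <- function(sequences, tf_constituents, pwms,
                         threshold = 0.8, hub_multiplier = 1) {
  net <- build_tf_network(sequences, tf_constituents, pwms, threshold)
  out_c <- closeness_centrality(net, "out")
  in_c <- closeness_centrality(net, "in")
  hubs <- hub_tfs(out_c, hub_multiplier)
  net$closeness <- tibble(tf = net$nodes,
                          closeness_out = unname(out_c[net$nodes]),
                          closeness_in = unname(in_c[net$nodes]),
                          hub = net$nodes %in% hubs)
  net$circuits <- find_circuits(net)
  net
}

#' Tidy a TF network into its node table
#'
#' @param x a `tf_network` from [crc_analysis()].
#' @param ... unused.
#' @return Tibble `tf, closeness_out, closeness_in, hub, in_circuit`.
#' @export
tidy.tf_network <- function(x, ...) {
  if (is.null(x$closeness)) {
    stopf("run crc_analysis() to populate centrality before tidying")
  }
  circuit_members <- unique(unlist(x$circuits))
  x$closeness %>% mutate(in_circuit = .data$tf %in% circuit_members)
}

#' @rdname tidy.tf_network
#' @export
glance.tf_network <- function(x, ...) {
  tibble(n_tfs = length(x$nodes), n_edges = nrow(x$edges),
         n_hubs = if (is.null(x$closeness)) NA_integer_ else
           sum(x$closeness$hub),
         n_circuits = if (is.null(x$circuits)) NA_integer_ else
           length(x$circuits))
}
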