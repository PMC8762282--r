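#' Position weight matrix object
#'
#' A PWM is a 4 x L base-probability matrix (rows A, C, G, T; columns
#' summing to 1 within 1e-6) with a motif ID, the TF gene it belongs to,
#' and background base frequencies used for log-odds scoring.
#'
#' @param id motif identifier.
#' @param tf TF gene symbol.
#' @param mat 4 x L probability matrix with rownames A, C, G, T.
#' @param background named base frequencies (default uniform).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(id, tf, mat,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!is.matrix(mat) || nrow(mat) != 4 ||
      !identical(rownames(mat), c("A", "C", "G", "T"))) {
    stopf("PWM matrix must be 4 x L with rownames A, C, G, T")
  }
  if (any(abs(colSums(mat) - 1) > 1e-6)) {
    stopf("PWM columns must sum to 1")
  }
  structure(list(id = id, tf = tf, mat = mat, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), %d bp, consensus %s\n", x$id, x$tf,
              ncol(x$mat), pwm_consensus(x)))
  invisible(x)
}

#' Build a near-deterministic PWM from a consensus string
#'
#' The consensus base gets probability 0.91 and the other bases 0.03
#' each, so an exact consensus match scores far above any single
#' mismatch at the usual relative thresholds.
#'
#' @param id,tf motif and TF identifiers.
#' @param consensus DNA string.
#' @return A [new_pwm()] object.
#' @export
consensus_pwm <- function(id, tf, consensus) {
  bases <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  mat <- matrix(0.03, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- 0.91
  new_pwm(id, tf, mat)
}

#' @rdname consensus_pwm
#' @param pwm a `pwm` object.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$mat)[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Scan a sequence for PWM hits on both strands
#'
#' Log-odds scoring against the PWM background; a window is a hit when
#' its score reaches `threshold` times the maximal attainable score.
#' The reverse strand is scanned on the reverse complement and hit
#' coordinates are reported on the forward frame (1-based, inclusive).
#' Windows containing N never match.
#'
#' @param sequence DNA string.
#' @param pwm a `pwm` object.
#' @param threshold fraction of the maximal score in (0, 1\]; default 0.8.
#' @return Tibble `start, end, strand, score`; empty when the sequence
#'   is shorter than the motif.
#' @export
scan_motifs <- function(sequence, pwm, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  L <- ncol(pwm$mat)
  lo <- log2(pmax(pwm$mat, 1e-6) /
               pwm$background[rownames(pwm$mat)])
  max_score <- sum(apply(lo, 2, max))
  cut <- threshold * max_score
  scan_one <- function(s) {
    W <- nchar(s)
    if (W < L) return(tibble(start = integer(), score = numeric()))
    code <- match(strsplit(s, "", fixed = TRUE)[[1]],
                  c("A", "C", "G", "T"))
    n_win <- W - L + 1
    scores <- rep(0, n_win)
    for (j in seq_len(L)) {
      b <- code[j:(j + n_win - 1)]
      col <- lo[, j]
      sc <- unname(col[b])
      sc[is.na(b)] <- -Inf
      scores <- scores + sc
    }
    hit <- which(scores >= cut)
    tibble(start = hit, score = scores[hit])
  }
  seq_up <- toupper(sequence)
  fwd <- scan_one(seq_up) %>% mutate(strand = "+")
  rev <- scan_one(reverse_complement(seq_up)) %>%
    mutate(start = nchar(seq_up) - (.data$start + L - 1) + 1,
           strand = "-")
  bind_rows(fwd, rev) %>%
    mutate(end = .data$start + L - 1) %>%
    select("start", "end", "strand", "score") %>%
    arrange(.data$start, .data$strand)
}
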