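#' Exact lower-tail binomial test for egg-laying rates
#'
#' P(X <= k | n, p0) for X ~ Binomial(n, p0): the probability of laying
#' at most `k` eggs in `n` hen-days when the pre-treatment laying rate
#' is `p0` (one-sided, alternative "less").
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials.
#' @param p0 baseline success rate in \[0, 1\].
#' @return Exact lower-tail probability.
#' @export
egg_binom_test <- function(k, n, p0) {
  assert_count(k, "k"); assert_count(n, "n")
  if (k > n) stopf("k must be <= n")
  if (p0 < 0 || p0 > 1) stopf("p0 must be in [0, 1]")
  pbinom(k, n, p0)
}

#' One-way ANOVA with LSD letter grouping
#'
#' Standard one-way ANOVA (via `stats::aov`); when the omnibus p-value
#' passes `alpha`, pairwise least-significant-difference t-tests on the
#' pooled mean-square error follow, summarised as letter groups: groups
#' sharing a letter are not significantly different. Letters are
#' assigned with the insert-and-absorb algorithm, which guarantees that
#' significantly different pairs never share a letter and
#' non-significant pairs share at least one.
#'
#' @param data data frame with the response and grouping columns.
#' @param value,group column names (strings) of the response and group.
#' @param alpha significance level (default 0.05).
#' @return An `lsd_result`: list with `f`, `p`, `df`, `mse`, `means`
#'   (tibble `group, mean, n, letter`), and `pairwise` (tibble
#'   `group1, group2, diff, t, p`; empty when the omnibus test fails).
#' @export
anova_lsd <- function(data, value = "value", group = "group",
                      alpha = 0.05) {
  data <- as_tibble(data)
  y <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 2) stopf("need >= 2 groups")
  if (any(table(g) < 2)) stopf("each group needs >= 2 values")
  fit <- aov(y ~ g)
  tab <- anova(fit)
  mse <- tab[["Mean Sq"]][2]
  if (!is.finite(mse) ||
      mse <= 1e-12 * (abs(tab[["Mean Sq"]][1]) + 1)) {
    stopf("zero within-group variance everywhere")
  }
  f <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
  df_err <- tab[["Df"]][2]
  means <- tibble(group = levels(g),
                  mean = as.numeric(tapply(y, g, mean)),
                  n = as.integer(table(g)))
  pairwise <- tibble(group1 = character(), group2 = character(),
                     diff = numeric(), t = numeric(), p = numeric())
  if (p <= alpha) {
    pairs <- combn(levels(g), 2)
    pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      m1 <- means$mean[means$group == g1]
      m2 <- means$mean[means$group == g2]
      n1 <- means$n[means$group == g1]; n2 <- means$n[means$group == g2]
      tval <- (m1 - m2) / sqrt(mse * (1 / n1 + 1 / n2))
      tibble(group1 = g1, group2 = g2, diff = m1 - m2, t = tval,
             p = 2 * pt(-abs(tval), df_err))
    })
  }
  means$letter <- lsd_letters(means, pairwise, alpha)
  structure(list(f = f, p = p, df = c(tab[["Df"]][1], df_err), mse = mse,
                 alpha = alpha, means = means, pairwise = pairwise),
            class = "lsd_result")
}

# insert-and-absorb letter assignment: start from one column holding all
# groups; for each significantly different pair split every column that
# contains both; absorb columns that became subsets of others
lsd_letters <- function(means, pairwise, alpha) {
  groups <- means$group[order(-means$mean)]
  cols <- list(groups)
  absorb <- function(cols) {
    cols <- unique(lapply(cols, sort))
    cols <- cols[vapply(cols, length, integer(1)) > 0]
    keep <- rep(TRUE, length(cols))
    for (x in seq_along(cols)) {
      for (z in seq_along(cols)) {
        if (x != z && keep[x] && keep[z] &&
            length(cols[[x]]) < length(cols[[z]]) &&
            all(cols[[x]] %in% cols[[z]])) {
          keep[x] <- FALSE
        }
      }
    }
    cols[keep]
  }
  sig <- pairwise %>% filter(.data$p <= alpha)
  if (nrow(sig) > 0) {
    for (i in seq_len(nrow(sig))) {
      a <- sig$group1[i]; b <- sig$group2[i]
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)),
                        list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      cols <- absorb(new_cols)
    }
  }
  # order columns by their best-ranked member, label a, b, c, ...
  first_rank <- vapply(cols, function(col)
    min(match(col, groups)), numeric(1))
  cols <- cols[order(first_rank)]
  letts <- letters[seq_along(cols)]
  vapply(means$group, function(gr) {
    paste(letts[vapply(cols, function(col) gr %in% col, logical(1))],
          collapse = "")
  }, character(1))
}

#' @export
print.lsd_result <- function(x, ...) {
  cat(sprintf("<lsd_result> F(%d, %d) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  print(x$means)
  invisible(x)
}

#' Tidy an ANOVA/LSD result
#'
#' @param x an `lsd_result`.
#' @param ... unused.
#' @return The per-group means with letter groups.
#' @export
tidy.lsd_result <- function(x, ...) x$means

#' @rdname tidy.lsd_result
#' @export
glance.lsd_result <- function(x, ...) {
  tibble(f = x$f, p = x$p, df1 = x$df[1], df2 = x$df[2], mse = x$mse)
}
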