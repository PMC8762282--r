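#' Plot the rank-signal hockey stick of super-enhancer calls
#'
#' @param object an `se_calls` tibble from [call_superenhancers()].
#' @param ... unused.
#' @return A ggplot: regions ordered by ascending signal, super-enhancers
#'   highlighted, the cutoff drawn as a horizontal line.
#' @method autoplot se_calls
#' @export
autoplot.se_calls <- function(object, ...) {
  df <- as_tibble(object) %>%
    arrange(.data$signal) %>%
    mutate(idx = row_number())
  thr <- attr(object, "threshold")
  p <- ggplot(df, aes(x = .data$idx, y = .data$signal,
                      colour = .data$is_super)) +
    geom_point(size = 0.8) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                        name = "super-enhancer") +
    labs(x = "regions ranked by H3K27ac signal", y = "region signal") +
    theme_minimal()
  if (is.finite(thr)) p <- p + geom_hline(yintercept = thr,
                                          linetype = "dashed")
  p
}

#' Plot a stage-alignment warp
#'
#' @param object a `stage_warp` from [align_stages()] or [dtw_warp()].
#' @param ... unused.
#' @return A ggplot of the cost matrix as a heat map with the optimal
#'   warping path overlaid.
#' @method autoplot stage_warp
#' @export
autoplot.stage_warp <- function(object, ...) {
  m <- object$cost
  df <- tibble(query = rep(seq_len(nrow(m)), ncol(m)),
               reference = rep(seq_len(ncol(m)), each = nrow(m)),
               cost = as.vector(m))
  ggplot(df, aes(x = .data$reference, y = .data$query,
                 fill = .data$cost)) +
    geom_tile() +
    geom_path(data = object$path, aes(x = .data$reference,
                                      y = .data$query),
              inherit.aes = FALSE, colour = "yellow", linewidth = 1) +
    scale_fill_viridis_c(name = "1 - Spearman") +
    scale_y_reverse() +
    labs(x = "reference stage", y = "query stage") +
    theme_minimal()
}

#' Plot a GSEA running sum
#'
#' @param object a `gsea_result` from [gsea_es()] or [gsea_p()].
#' @param ... unused.
#' @return A ggplot of the running enrichment score with hit positions
#'   as a rug.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- object$running
  ggplot(df, aes(x = .data$index, y = .data$running)) +
    geom_line(colour = "darkgreen") +
    geom_hline(yintercept = 0, linetype = "dotted") +
    geom_rug(data = df[df$hit, ], sides = "b", colour = "black") +
    geom_vline(xintercept = object$extremum_index, linetype = "dashed",
               colour = "red") +
    labs(x = "gene rank", y = "running enrichment score") +
    theme_minimal()
}

#' Plot a TF network's closeness landscape
#'
#' @param object a `tf_network` from [crc_analysis()].
#' @param ... unused.
#' @return A ggplot of out- vs in-closeness per TF, hubs highlighted.
#' @method autoplot tf_network
#' @export
autoplot.tf_network <- function(object, ...) {
  if (is.null(object$closeness)) {
    stopf("run crc_analysis() before plotting")
  }
  ggplot(object$closeness,
         aes(x = .data$closeness_in, y = .data$closeness_out,
             colour = .data$hub, label = .data$tf)) +
    geom_point(size = 2) +
    geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    scale_colour_manual(values = c(`FALSE` = "grey40",
                                   `TRUE` = "purple"),
                        name = "hub TF") +
    labs(x = "closeness centrality (in)",
         y = "closeness centrality (out)") +
    theme_minimal()
}
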