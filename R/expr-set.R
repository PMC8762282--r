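#' Expression set container
#'
#' A light container pairing a gene-by-sample expression matrix with a
#' per-sample metadata table. Values are FPKM (non-negative) unless the
#' object carries the `log2` flag, in which case they are on the
#' log2(FPKM + 1) working scale (batch-corrected output lives on that
#' scale, where location-scale adjustment can legitimately dip below 0).
#'
#' @param values numeric matrix, genes in rows, samples in columns; column
#'   names must match `sample_meta$sample_id`.
#' @param sample_meta data frame with columns `sample_id`, `species`,
#'   `compartment` (`"GC"` or `"TC"`), `stage`, `stage_order` (integer,
#'   non-decreasing within a species/compartment), `replicate`, `batch`.
#' @param log2 logical; `TRUE` when `values` are on the log2(FPKM+1) scale.
#'
#' @return An object of class `follicle_expr`.
#' @export
follicle_expr <- function(values, sample_meta, log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  sample_meta <- as_tibble(sample_meta)
  needed <- c("sample_id", "species", "compartment", "stage",
              "stage_order", "replicate", "batch")
  missing_cols <- setdiff(needed, names(sample_meta))
  if (length(missing_cols) > 0) {
    stopf("sample_meta lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (is.null(colnames(values)) || (nrow(values) > 0 &&
                                    is.null(rownames(values)))) {
    stopf("`values` must have gene row names and sample column names")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (anyDuplicated(colnames(values)) > 0) stopf("duplicate sample IDs")
  if (!identical(colnames(values), sample_meta$sample_id)) {
    sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
    if (anyNA(sample_meta$sample_id)) {
      stopf("sample_meta rows do not match matrix columns")
    }
  }
  if (!log2 && any(values < 0)) stopf("negative FPKM values")
  bad <- sample_meta %>%
    arrange(.data$species, .data$compartment, .data$stage_order) %>%
    group_by(.data$species, .data$compartment, .data$stage) %>%
    summarise(n_order = n_distinct(.data$stage_order), .groups = "drop") %>%
    filter(.data$n_order > 1)
  if (nrow(bad) > 0) {
    stopf("stage labels map to multiple stage_order values within a species")
  }
  structure(list(values = values, sample_meta = sample_meta, log2 = log2),
            class = "follicle_expr")
}

#' @export
print.follicle_expr <- function(x, ...) {
  cat(sprintf("<follicle_expr> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2(FPKM+1)" else "FPKM"))
  cat(sprintf("  species: %s\n",
              paste(unique(x$sample_meta$species), collapse = ", ")))
  invisible(x)
}

#' @export
dim.follicle_expr <- function(x) dim(x$values)

#' Tidy an expression set into a long tibble
#'
#' @param x a [follicle_expr] object.
#' @param ... unused.
#' @return A tibble with one row per gene/sample pair, joined to the
#'   sample metadata. The value column is `fpkm` or `log2_fpkm` depending
#'   on the object's scale.
#' @export
tidy.follicle_expr <- function(x, ...) {
  val_col <- if (x$log2) "log2_fpkm" else "fpkm"
  as_tibble(x$values, rownames = "gene_id") %>%
    pivot_longer(-"gene_id", names_to = "sample_id", values_to = val_col) %>%
    left_join(x$sample_meta, by = "sample_id")
}

#' Build an expression set from a long tibble
#'
#' Inverse of [tidy.follicle_expr()]: takes a long table with one row per
#' gene/sample pair plus metadata columns and reassembles the container.
#'
#' @param data long tibble with `gene_id`, `sample_id`, a value column
#'   (`fpkm` or `log2_fpkm`), and the metadata columns.
#' @return A [follicle_expr] object.
#' @export
as_follicle_expr <- function(data) {
  data <- as_tibble(data)
  log2 <- "log2_fpkm" %in% names(data)
  val_col <- if (log2) "log2_fpkm" else "fpkm"
  wide <- data %>%
    select("gene_id", "sample_id", all_of(val_col)) %>%
    pivot_wider(names_from = "sample_id", values_from = all_of(val_col))
  values <- as.matrix(wide[, -1, drop = FALSE])
  rownames(values) <- wide$gene_id
  meta <- data %>%
    select("sample_id", "species", "compartment", "stage", "stage_order",
           "replicate", "batch") %>%
    distinct()
  follicle_expr(values, meta, log2 = log2)
}

# subset samples by a metadata predicate, keeping classes intact
subset_samples <- function(es, keep) {
  stopifnot(inherits(es, "follicle_expr"))
  follicle_expr(es$values[, keep, drop = FALSE],
                es$sample_meta[keep, , drop = FALSE], log2 = es$log2)
}
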