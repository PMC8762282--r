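#' Read and write the pipeline's plain-text formats
#'
#' All genomic coordinates are 0-based half-open (BED convention).
#' Expression matrices travel as TSV with a `gene_id` column followed by
#' one column per sample; metadata as TSV with the fixed columns
#' `sample_id, species, compartment, stage, stage_order, replicate, batch`.
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @param es a [follicle_expr] object.
#' @export
write_expr_tsv <- function(es, path) {
  as_tibble(es$values, rownames = "gene_id") %>% write_tsv(path)
  invisible(path)
}

#' @rdname io
#' @param meta sample metadata tibble (written alongside the matrix).
#' @export
write_sample_meta <- function(meta, path) {
  write_tsv(as_tibble(meta), path)
  invisible(path)
}

#' @rdname io
#' @export
read_expr_tsv <- function(path, meta_path) {
  tab <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$gene_id
  meta <- read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  follicle_expr(values, meta)
}

#' @rdname io
#' @param orthologs long tibble `group_id, species, gene_id`.
#' @export
write_ortholog_table <- function(orthologs, path) {
  write_tsv(as_tibble(orthologs), path)
  invisible(path)
}

#' @rdname io
#' @export
read_ortholog_table <- function(path) {
  read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- read_lines(path)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    tibble(term = f[1], description = f[2], gene = f[-(1:2)])
  })
}

#' @rdname io
#' @param annotation long tibble `term, gene` (optional `description`).
#' @export
write_gmt <- function(annotation, path) {
  annotation <- as_tibble(annotation)
  if (!"description" %in% names(annotation)) annotation$description <- "na"
  lines <- annotation %>%
    group_by(.data$term) %>%
    summarise(line = paste(c(.data$term[1], .data$description[1],
                             .data$gene), collapse = "\t"),
              .groups = "drop")
  write_lines(lines$line, path)
  invisible(path)
}

bed_cols <- c("chrom", "start", "end", "name", "score", "strand")

#' @rdname io
#' @export
read_bed6 <- function(path) {
  read_tsv(path, col_names = bed_cols, show_col_types = FALSE,
           progress = FALSE)
}

#' @rdname io
#' @param bed tibble with at least `chrom, start, end`; `name`, `score`,
#'   `strand` filled with placeholders when absent.
#' @export
write_bed6 <- function(bed, path) {
  bed <- as_tibble(bed)
  if (!"name" %in% names(bed)) bed$name <- paste0("r", seq_len(nrow(bed)))
  if (!"score" %in% names(bed)) bed$score <- 0
  if (!"strand" %in% names(bed)) bed$strand <- "+"
  write_tsv(bed[, bed_cols], path, col_names = FALSE)
  invisible(path)
}

np_cols <- c(bed_cols, "signal_value", "p_value", "q_value", "peak_offset")

#' @rdname io
#' @export
read_narrowpeak <- function(path) {
  read_tsv(path, col_names = np_cols, show_col_types = FALSE,
           progress = FALSE)
}

#' @rdname io
#' @param peaks tibble with at least `chrom, start, end, name`.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- as_tibble(peaks)
  defaults <- list(score = 0, strand = ".", signal_value = 0,
                   p_value = -1, q_value = -1, peak_offset = -1)
  for (nm in names(defaults)) {
    if (!nm %in% names(peaks)) peaks[[nm]] <- defaults[[nm]]
  }
  write_tsv(peaks[, np_cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bedgraph <- function(path) {
  read_tsv(path, col_names = c("chrom", "start", "end", "value"),
           show_col_types = FALSE, progress = FALSE)
}

#' @rdname io
#' @param track bedGraph tibble `chrom, start, end, value`.
#' @export
write_bedgraph <- function(track, path) {
  write_tsv(as_tibble(track)[, c("chrom", "start", "end", "value")],
            path, col_names = FALSE)
  invisible(path)
}

#' Read a MAF multiple-alignment file
#'
#' Parses alignment blocks into a long tibble, one row per species row
#' per block. Minus-strand rows are reverse-complemented on read and
#' their start coordinate converted to the forward frame, so all
#' downstream profiles live on the reference (plus) frame.
#'
#' @param path MAF file path.
#' @return Tibble `block_id, species, chrom, start, size, strand,
#'   src_size, text`.
#' @export
read_maf <- function(path) {
  lines <- read_lines(path)
  out <- list()
  block <- 0L
  for (l in lines) {
    if (startsWith(l, "a")) {
      block <- block + 1L
    } else if (startsWith(l, "s")) {
      f <- strsplit(trimws(l), "[ \t]+")[[1]]
      src <- strsplit(f[2], ".", fixed = TRUE)[[1]]
      species <- src[1]
      chrom <- paste(src[-1], collapse = ".")
      start <- as.numeric(f[3]); size <- as.numeric(f[4])
      strand <- f[5]; src_size <- as.numeric(f[6]); text <- f[7]
      if (strand == "-") {
        text <- reverse_complement(text)
        start <- src_size - start - size
        strand <- "+"
      }
      out[[length(out) + 1L]] <- tibble(
        block_id = block, species = species, chrom = chrom,
        start = start, size = size, strand = strand,
        src_size = src_size, text = text)
    }
  }
  bind_rows(out)
}

#' @rdname io
#' @param blocks tibble as returned by [read_maf()].
#' @export
write_maf <- function(blocks, path) {
  blocks <- as_tibble(blocks)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in unique(blocks$block_id)) {
    rows <- blocks[blocks$block_id == b, ]
    writeLines("a score=0", con)
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      writeLines(sprintf("s %s.%s %d %d %s %d %s",
                         r$species, r$chrom, as.integer(r$start),
                         as.integer(r$size), r$strand,
                         as.integer(r$src_size), r$text), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read and write position weight matrices
#'
#' JASPAR-style text: a `>motif_id tf_name` header followed by four
#' lines `A [ p p p ... ]` (probabilities, columns summing to 1).
#'
#' @param path file path.
#' @return A named list of PWM objects (see [new_pwm()]).
#' @export
read_pwms <- function(path) {
  lines <- read_lines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  pwms <- list()
  for (i in seq_along(heads)) {
    h <- strsplit(sub("^>", "", lines[heads[i]]), "[ \t]+")[[1]]
    rows <- lines[heads[i] + 1:4]
    vals <- lapply(rows, function(r) {
      nums <- gsub("^[ACGT]\\s*\\[|\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(nums), "[ \t]+")[[1]])
    })
    mat <- do.call(rbind, vals)
    rownames(mat) <- c("A", "C", "G", "T")
    pwms[[h[1]]] <- new_pwm(h[1], if (length(h) > 1) h[2] else h[1], mat)
  }
  pwms
}

#' @rdname read_pwms
#' @param pwms named list of PWM objects.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$tf), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$mat[b, ], digits = 6),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname io
#' @param seqs named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname io
#' @param truth synthetic-truth list.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname io
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
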