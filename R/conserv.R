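#' Extract the alignment slice homologous to a reference interval
#'
#' Selects alignment columns whose reference position falls in
#' `ref_interval`, concatenated across blocks in reference order. A
#' species absent from a block contributes gap characters for that
#' block's columns, and reference bases covered by no block at all are
#' emitted as `N` on the reference row with gaps for every other
#' species — absence of alignment is treated as the strongest deletion
#' signal.
#'
#' @param blocks alignment tibble from [read_maf()] (minus-strand rows
#'   already normalised to the forward frame).
#' @param ref_interval list or one-row tibble with `chrom, start, end`
#'   (0-based half-open, reference coordinates).
#' @param ref_species reference species name.
#' @return List with `slices` (named aligned strings, equal length),
#'   `sequences` (named ungapped strings), and `width` (columns).
#'   Empty (with a warning) if the interval overlaps no block.
#' @export
extract_homolog <- function(blocks, ref_interval, ref_species) {
  blocks <- as_tibble(blocks)
  species <- unique(blocks$species)
  iv_start <- ref_interval$start; iv_end <- ref_interval$end
  ref_rows <- blocks %>%
    filter(.data$species == ref_species,
           .data$chrom == ref_interval$chrom,
           .data$start < iv_end, .data$start + .data$size > iv_start) %>%
    arrange(.data$start)
  if (nrow(ref_rows) == 0) {
    warnf("interval overlaps no alignment block")
    return(list(slices = setNames(rep("", length(species)), species),
                sequences = setNames(rep("", length(species)), species),
                width = 0L))
  }
  pieces <- setNames(vector("list", length(species)), species)
  cursor <- iv_start
  pad_all <- function(n_cols) {
    for (sp in species) {
      pieces[[sp]][[length(pieces[[sp]]) + 1]] <<-
        if (sp == ref_species) strrep("N", n_cols) else strrep("-", n_cols)
    }
  }
  for (bi in seq_len(nrow(ref_rows))) {
    rr <- ref_rows[bi, ]
    if (rr$start > cursor) pad_all(rr$start - cursor)  # uncovered gap
    block <- blocks %>% filter(.data$block_id == rr$block_id)
    ref_text <- rr$text
    chars <- strsplit(ref_text, "", fixed = TRUE)[[1]]
    is_base <- chars != "-"
    ref_pos <- rr$start + cumsum(is_base) - 1  # ref position per column
    ref_pos[!is_base] <- NA
    keep_cols <- which(!is.na(ref_pos) & ref_pos >= max(iv_start, cursor) &
                         ref_pos < iv_end)
    if (length(keep_cols) == 0) next
    for (sp in species) {
      row <- block %>% filter(.data$species == sp)
      txt <- if (nrow(row) == 0) strrep("-", nchar(ref_text)) else
        row$text[1]
      cc <- strsplit(txt, "", fixed = TRUE)[[1]][keep_cols]
      pieces[[sp]][[length(pieces[[sp]]) + 1]] <- paste(cc, collapse = "")
    }
    cursor <- max(cursor, max(ref_pos, na.rm = TRUE) + 1)
  }
  if (cursor < iv_end) pad_all(iv_end - cursor)
  slices <- vapply(pieces, function(p) paste(unlist(p), collapse = ""),
                   character(1))
  list(slices = slices,
       sequences = vapply(slices, function(s) gsub("-", "", s),
                          character(1)),
       width = nchar(slices[[1]]))
}

#' Per-species gap fraction of an aligned slice
#'
#' @param slices named character vector of equal-length aligned strings.
#' @return Named numeric vector in \[0, 1\]; the reference row of a
#'   [extract_homolog()] result is always 0.
#' @export
gap_fraction <- function(slices) {
  w <- unique(nchar(slices))
  if (length(w) != 1 || w == 0) stopf("slices must share a non-zero length")
  vapply(slices, function(s) str_count(s, stringr::fixed("-")) / nchar(s),
         numeric(1))
}

#' Cross-species TF binding profile of homologous sequences
#'
#' Counts PWM hits (via [scan_motifs()]) in each species' ungapped
#' homologous sequence.
#'
#' @param sequences named character vector of ungapped sequences.
#' @param pwms named list of `pwm` objects.
#' @param threshold motif-scan threshold.
#' @return Tibble `species, tf, hits` (long species x TF count matrix).
#' @export
binding_profile <- function(sequences, pwms, threshold = 0.8) {
  purrr::imap_dfr(as.list(sequences), function(s, sp) {
    purrr::map_dfr(pwms, function(p) {
      tibble(species = sp, tf = p$tf,
             hits = if (nchar(s) == 0) 0L else
               nrow(scan_motifs(s, p, threshold)))
    })
  })
}

#' Clade-specificity verdict for one interval
#'
#' `"clade-specific"` when every clade member's gap fraction is at most
#' `max_gap` and every non-member (reference aside) is above it;
#' `"not-conserved"` when no species besides the reference is at or
#' below `max_gap`; otherwise `"shared"`.
#'
#' @param gap_fractions named numeric vector from [gap_fraction()].
#' @param clade character vector of clade member species.
#' @param ref_species reference species (excluded from the rule).
#' @param max_gap gap-fraction threshold (default 0.5).
#' @return One of `"clade-specific"`, `"shared"`, `"not-conserved"`.
#' @export
clade_specificity <- function(gap_fractions, clade, ref_species,
                              max_gap = 0.5) {
  sp <- setdiff(names(gap_fractions), ref_species)
  if (!all(clade %in% c(names(gap_fractions), ref_species))) {
    stopf("clade is not a subset of the species list")
  }
  clade <- setdiff(clade, ref_species)
  inside <- gap_fractions[intersect(sp, clade)]
  outside <- gap_fractions[setdiff(sp, clade)]
  conserved_any <- any(gap_fractions[sp] <= max_gap)
  if (!conserved_any) return("not-conserved")
  if (length(inside) > 0 && all(inside <= max_gap) &&
      (length(outside) == 0 || all(outside > max_gap))) {
    return("clade-specific")
  }
  "shared"
}

#' Conservation verdicts for a set of reference intervals
#'
#' Runs [extract_homolog()], [gap_fraction()] and [clade_specificity()]
#' over each query interval.
#'
#' @param blocks alignment tibble from [read_maf()].
#' @param intervals tibble `chrom, start, end, name`.
#' @param clade clade member species.
#' @param ref_species reference species.
#' @param max_gap gap-fraction threshold.
#' @return Tibble `name, verdict, n_species, width` plus a `gap`
#'   list-column of per-species fractions.
#' @export
conservation_verdicts <- function(blocks, intervals, clade, ref_species,
                                  max_gap = 0.5) {
  intervals <- as_tibble(intervals)
  purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    hom <- extract_homolog(blocks, iv, ref_species)
    gf <- gap_fraction(hom$slices)
    tibble(name = iv$name,
           verdict = clade_specificity(gf, clade, ref_species, max_gap),
           n_species = length(gf), width = hom$width, gap = list(gf))
  })
}
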