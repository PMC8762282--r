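#' Stitch enhancer peaks into candidate regions
#'
#' ROSE-style stitching: peaks on the same chromosome whose gap is at
#' most `stitch_dist` are merged into one region. Peaks lying entirely
#' within `tss_excl` of a TSS are removed before stitching (promoter
#' exclusion). Coordinates are 0-based half-open throughout.
#'
#' @param peaks tibble with `chrom, start, end, name`.
#' @param stitch_dist maximum gap to merge across (bp, default 12500).
#' @param tss optional TSS tibble (`chrom, start, end, name`); when
#'   given, promoter-proximal peaks are excluded.
#' @param tss_excl promoter exclusion half-window (bp, default 2500).
#' @return Tibble `chrom, start, end, region_id, constituents` (list
#'   column of peak names), `n_constituents`, sorted by coordinate.
#' @export
stitch_peaks <- function(peaks, stitch_dist = 12500, tss = NULL,
                         tss_excl = 2500) {
  peaks <- as_tibble(peaks)
  if (any(peaks$end <= peaks$start)) stopf("malformed interval: end <= start")
  if (!"name" %in% names(peaks)) {
    peaks$name <- paste0("peak", seq_len(nrow(peaks)))
  }
  if (!is.null(tss) && nrow(peaks) > 0) {
    pk <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(peaks$start + 1, peaks$end))
    tz <- GenomicRanges::GRanges(
      tss$chrom, IRanges::IRanges(pmax(tss$start + 1 - tss_excl, 1),
                                  tss$end + tss_excl))
    inside <- IRanges::overlapsAny(pk, tz, type = "within")
    peaks <- peaks[!inside, , drop = FALSE]
  }
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  region_id = character(), constituents = list(),
                  n_constituents = integer()))
  }
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_dist + 1,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    constituents = lapply(revmap, function(i) peaks$name[i])) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(region_id = sprintf("region%05d", row_number()),
           n_constituents = purrr::map_int(.data$constituents, length)) %>%
    select("chrom", "start", "end", "region_id", "constituents",
           "n_constituents")
  out
}

# error if any two intervals of one bedGraph track overlap
check_track <- function(track) {
  track <- as_tibble(track) %>% arrange(.data$chrom, .data$start)
  bad <- track %>%
    group_by(.data$chrom) %>%
    summarise(ov = any(.data$start[-1] < head(.data$end, -1)),
              .groups = "drop")
  if (any(bad$ov)) stopf("overlapping intervals within one signal track")
  track
}

#' Background-subtracted signal over regions
#'
#' Interval-length-weighted sum of (signal - control) over each region,
#' floored at 0 — the area under the bedGraph track minus the matched
#' control area. Positions without coverage contribute 0.
#'
#' @param regions tibble with `chrom, start, end` (plus any id columns,
#'   preserved).
#' @param signal bedGraph tibble `chrom, start, end, value`; intervals
#'   within the track must not overlap.
#' @param control optional bedGraph of the same form, subtracted
#'   base-by-base.
#' @return The `regions` tibble with a `signal` column appended.
#' @export
region_signal <- function(regions, signal, control = NULL) {
  regions <- as_tibble(regions)
  signal <- check_track(signal)
  if (!is.null(control)) control <- check_track(control)
  area <- function(track) {
    if (nrow(regions) == 0 || nrow(track) == 0) {
      return(numeric(nrow(regions)))
    }
    rg <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1,
                                                  regions$end))
    tg <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1,
                                                  track$end))
    hits <- GenomicRanges::findOverlaps(rg, tg)
    if (length(hits) == 0) return(numeric(nrow(regions)))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- pmin(regions$end[q], track$end[s]) -
      pmax(regions$start[q], track$start[s])
    tapply_sum <- rep(0, nrow(regions))
    contrib <- ov * track$value[s]
    for (i in seq_along(q)) tapply_sum[q[i]] <- tapply_sum[q[i]] + contrib[i]
    tapply_sum
  }
  sig <- area(signal)
  if (!is.null(control)) sig <- sig - area(control)
  regions$signal <- pmax(sig, 0)
  regions
}

#' Hockey-stick super-enhancer cutoff
#'
#' Sorts region signals ascending and min-max scales both ranks and
#' signals to \[0, 1\]. The cutoff sits where a line of slope 1 is
#' tangent to the scaled rank-signal curve — the rank minimising
#' `scaled signal - scaled rank`, i.e. the point after which the curve
#' rises faster than the diagonal for good. Ties (as on a perfectly
#' linear ramp) resolve to the last rank, so a ramp and all-equal
#' signals both yield no super-enhancer. Regions with signal strictly
#' above the signal at the tangent rank are flagged super-enhancers.
#'
#' @param signals numeric vector of region signals (>= 3 values).
#' @return List with `threshold` (signal value at the cutoff rank; `Inf`
#'   for degenerate all-equal input), `is_super` (logical, input
#'   order), and `cutoff_rank` (ascending rank of the threshold, `NA`
#'   when degenerate).
#' @export
hockey_stick_cutoff <- function(signals) {
  if (length(signals) < 3) stopf("need >= 3 regions")
  ord <- order(signals)
  s <- signals[ord]
  n <- length(s)
  rng <- s[n] - s[1]
  if (rng <= 0) {
    return(list(threshold = Inf, is_super = rep(FALSE, n),
                cutoff_rank = NA_integer_))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / rng
  gap <- y - x
  cutoff_rank <- max(which(gap <= min(gap) + 1e-12))
  threshold <- s[cutoff_rank]
  list(threshold = threshold, is_super = signals > threshold,
       cutoff_rank = cutoff_rank)
}

#' Assign genes to regions by TSS proximity
#'
#' A gene is assigned to a region when its TSS lies within the region
#' extended by `window` on both sides; all qualifying genes are kept.
#'
#' @param regions tibble with `chrom, start, end, region_id`.
#' @param tss TSS tibble `chrom, start, end, name` (name = gene).
#' @param window assignment window (bp, default 50000).
#' @return Tibble `region_id, gene`, one row per assignment.
#' @export
assign_genes <- function(regions, tss, window = 50000) {
  regions <- as_tibble(regions); tss <- as_tibble(tss)
  if (nrow(regions) == 0 || nrow(tss) == 0) {
    return(tibble(region_id = character(), gene = character()))
  }
  # a TSS at exactly start - window or end + window (0-based) is
  # assigned; one base further out is not
  rg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(pmax(regions$start + 1 - window, 1),
                                    regions$end + window + 1))
  tz <- GenomicRanges::GRanges(tss$chrom,
                               IRanges::IRanges(tss$start + 1, tss$end))
  hits <- GenomicRanges::findOverlaps(rg, tz)
  tibble(region_id = regions$region_id[S4Vectors::queryHits(hits)],
         gene = tss$name[S4Vectors::subjectHits(hits)]) %>%
    distinct()
}

#' Call super-enhancers from peaks and signal
#'
#' The full ROSE-style pipeline: promoter-filtered stitching, region
#' signal, hockey-stick cutoff, descending-signal ranking, and gene
#' assignment.
#'
#' @inheritParams stitch_peaks
#' @inheritParams region_signal
#' @inheritParams assign_genes
#' @return An `se_calls` tibble: stitched regions with `signal`, `rank`
#'   (1 = strongest), `is_super`, and a `genes` list column; the cutoff
#'   is stored in the `threshold` attribute.
#' @export
call_superenhancers <- function(peaks, signal, tss, control = NULL,
                                stitch_dist = 12500, tss_excl = 2500,
                                window = 50000) {
  regions <- stitch_peaks(peaks, stitch_dist = stitch_dist, tss = tss,
                          tss_excl = tss_excl)
  regions <- region_signal(regions, signal, control)
  cut <- hockey_stick_cutoff(regions$signal)
  assignments <- assign_genes(regions, tss, window = window)
  gene_map <- split(assignments$gene, assignments$region_id)
  out <- regions %>%
    mutate(rank = rank(-.data$signal, ties.method = "first"),
           is_super = cut$is_super,
           genes = unname(gene_map[.data$region_id]),
           genes = purrr::map(.data$genes, function(g)
             if (is.null(g)) character() else g)) %>%
    arrange(.data$rank)
  attr(out, "threshold") <- cut$threshold
  class(out) <- c("se_calls", class(out))
  out
}
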