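#' Generate multiple-alignment blocks with clade-structured gap patterns
#'
#' Emulates a reference-anchored vertebrate multiple alignment: the
#' reference (first species) row is gap-free, and every other species row
#' receives independent per-column gaps at a rate that depends on the
#' planted class of the interval the block covers:
#'
#' * `clade_conserved` intervals: clade members gap at `gap_rate_in`,
#'   all other species at `gap_rate_out`;
#' * `shared` intervals: every species gaps at `gap_rate_in`;
#' * `not_conserved` intervals: every non-reference species gaps at
#'   `gap_rate_out_deep`.
#'
#' Aligned length equals the reference length (no insertions relative to
#' the reference), so alignment columns index reference positions.
#'
#' @param n_species total species count including the reference.
#' @param clade character vector of clade member names (subset of the
#'   emitted species, reference excluded from the gap model).
#' @param gap_rate_in per-column gap probability inside conserved rows.
#' @param gap_rate_out per-column gap probability for outgroup rows in
#'   clade-conserved intervals (`0 <= gap_rate_in < gap_rate_out <= 1`).
#' @param gap_rate_out_deep gap probability in `not_conserved` intervals.
#' @param n_conserved,n_shared,n_nonconserved planted interval counts.
#' @param interval_length reference length of each planted interval (bp).
#' @param ref_species,ref_chrom reference row naming.
#' @param motif_consensus optional DNA string planted (gap-free) into
#'   clade rows of clade-conserved intervals, so binding profiles light
#'   up only in the clade.
#' @param seed RNG seed.
#'
#' @return List with `blocks` (tibble as from [read_maf()]), `intervals`
#'   (BED-style tibble of planted intervals with their class), and
#'   `truth` (interval verdicts, clade, per-interval conserved species).
#' @export
generate_alignment_blocks <- function(n_species = 77,
                                      clade = NULL,
                                      gap_rate_in = 0.05,
                                      gap_rate_out = 0.6,
                                      gap_rate_out_deep = 0.8,
                                      n_conserved = 2, n_shared = 1,
                                      n_nonconserved = 1,
                                      interval_length = 1200,
                                      ref_species = "galGal",
                                      ref_chrom = "chr1",
                                      motif_consensus = NULL,
                                      seed = 1) {
  assert_count(n_species, "n_species", positive = TRUE)
  if (gap_rate_in < 0 || gap_rate_out > 1 || gap_rate_in >= gap_rate_out) {
    stopf("need 0 <= gap_rate_in < gap_rate_out <= 1")
  }
  n_other <- n_species - 1
  others <- c(sprintf("bird%02d", seq_len(min(14, n_other))),
              if (n_other > 14) sprintf("out%02d", seq_len(n_other - 14)))
  species <- c(ref_species, others)
  if (is.null(clade)) clade <- grep("^bird", others, value = TRUE)
  if (!all(clade %in% species)) stopf("clade is not a subset of the species")
  withr::with_seed(seed, {
    classes <- c(rep("clade_conserved", n_conserved),
                 rep("shared", n_shared),
                 rep("not_conserved", n_nonconserved))
    blocks <- list(); intervals <- list()
    pos <- 5000
    for (i in seq_along(classes)) {
      cls <- classes[i]
      L <- interval_length
      ref_seq <- random_dna(L)
      rows <- list(tibble(block_id = i, species = ref_species,
                          chrom = ref_chrom, start = pos, size = L,
                          strand = "+", src_size = 10 * (pos + L),
                          text = ref_seq))
      for (sp in others) {
        rate <- switch(cls,
          clade_conserved = if (sp %in% clade) gap_rate_in else gap_rate_out,
          shared = gap_rate_in,
          not_conserved = gap_rate_out_deep)
        gaps <- runif(L) < rate
        txt <- strsplit(random_dna(L), "", fixed = TRUE)[[1]]
        txt[gaps] <- "-"
        txt <- paste(txt, collapse = "")
        if (!is.null(motif_consensus) && cls == "clade_conserved" &&
            sp %in% clade) {
          off <- 101
          substr(txt, off, off + nchar(motif_consensus) - 1) <-
            motif_consensus
        }
        rows[[length(rows) + 1]] <- tibble(
          block_id = i, species = sp, chrom = "chrA", start = 0,
          size = nchar(gsub("-", "", txt)), strand = "+",
          src_size = 10 * L, text = txt)
      }
      if (!is.null(motif_consensus) && cls == "clade_conserved") {
        substr(ref_seq, 101, 100 + nchar(motif_consensus)) <- motif_consensus
        rows[[1]]$text <- ref_seq
      }
      blocks[[i]] <- bind_rows(rows)
      intervals[[i]] <- tibble(chrom = ref_chrom, start = pos,
                               end = pos + L,
                               name = sprintf("iv%02d", i), class = cls)
      pos <- pos + L + 3000
    }
    blocks <- bind_rows(blocks)
    intervals <- bind_rows(intervals)
    verdict_of <- c(clade_conserved = "clade-specific", shared = "shared",
                    not_conserved = "not-conserved")
    truth <- list(
      species = species, clade = clade, ref_species = ref_species,
      planted_intervals = intervals,
      planted_verdicts = as.list(setNames(unname(verdict_of[intervals$class]),
                                          intervals$name)),
      planted_clade_conserved = setNames(
        lapply(intervals$class, function(cl) {
          switch(cl, clade_conserved = c(ref_species, clade),
                 shared = species, not_conserved = ref_species)
        }), intervals$name),
      seeds = list(alignment = seed))
    list(blocks = blocks, intervals = intervals, truth = truth)
  })
}
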