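#' Generate a synthetic H3K27ac landscape with planted super-enhancers
#'
#' Lays typical enhancers (isolated 1-kb peaks, per-bp amplitude
#' LogNormal(0, `typical_log_sd`)) and super-enhancer clusters
#' (`se_cluster_size` constituents at `se_fold`x the typical amplitude,
#' gaps well inside the stitch distance) along one synthetic chromosome,
#' with one associated gene TSS per region. The first planted SEs are
#' assigned to the transcription factors in `tf_genes`; exact PWM
#' consensus substrings are planted inside designated SE constituents so
#' that the implied TF regulatory graph is recovered deterministically:
#' the first TF is the hub (its consensus sits in every SE constituent),
#' TFs 2-4 form a fully interconnected circuit, TF5 targets TF6.
#'
#' @param n_enh number of typical (non-super) enhancers.
#' @param n_se number of planted super-enhancer clusters (< `n_enh`).
#' @param se_cluster_size constituent peaks per planted SE.
#' @param tf_genes TF gene symbols receiving SEs, PWMs, and planted
#'   motif occurrences (needs `n_se >= length(tf_genes)` unless 0 SEs).
#' @param enh_width constituent peak width (bp).
#' @param gap_within gap between constituents inside a planted SE (bp);
#'   must stay below the intended stitch distance.
#' @param spacing distance between neighbouring regions (bp); large
#'   enough that regions neither stitch together nor fall inside each
#'   other's gene-assignment window.
#' @param typical_log_sd log-scale SD of the typical per-bp amplitude.
#' @param se_fold amplitude fold of SE constituents over typical.
#' @param motif_length planted consensus length (bp); 12 keeps spurious
#'   exact matches over the whole fixture below expectation 0.1.
#' @param tss_offset distance from region end to the associated TSS (bp).
#' @param seed RNG seed.
#'
#' @return List with `peaks` (narrowPeak tibble), `signal` (bedGraph
#'   tibble), `tss` (BED6 tibble with gene names), `pwms` (named list of
#'   PWM objects), `sequences` (named per-peak DNA), and `truth`
#'   (planted SE spans, network edges, hub, circuit, consensus strings).
#' @export
generate_epigenome <- function(n_enh = 400, n_se = 20, se_cluster_size = 3,
                               tf_genes = paste0("TF", 1:6),
                               enh_width = 1000, gap_within = 2000,
                               spacing = 80000, typical_log_sd = 0.08,
                               se_fold = 16, motif_length = 12,
                               tss_offset = 5000, seed = 1) {
  assert_count(n_enh, "n_enh", positive = TRUE)
  assert_count(n_se, "n_se")
  assert_count(se_cluster_size, "se_cluster_size", positive = TRUE)
  if (n_se >= n_enh) stopf("n_se must be < n_enh")
  if (n_se > 0 && n_se < length(tf_genes)) {
    stopf("need at least one SE per TF gene")
  }
  withr::with_seed(seed, {
    n_tf <- length(tf_genes)
    consensus <- character(n_tf)
    repeat {  # distinct consensus strings; shifted regeneration on clash
      consensus <- vapply(seq_len(n_tf), function(i) random_dna(motif_length),
                          character(1))
      if (anyDuplicated(consensus) == 0) break
    }
    names(consensus) <- tf_genes
    pwms <- purrr::imap(setNames(as.list(consensus), tf_genes),
                        function(cs, tf) consensus_pwm(paste0("M_", tf),
                                                       tf, cs))

    # region layout: SE clusters first, then typicals, sequentially placed
    region_kind <- c(rep("SE", n_se), rep("typical", n_enh))
    peaks <- list(); signal <- list(); tss <- list(); seqs <- list()
    se_truth <- list(); constituents_of_se <- list()
    pos <- 10000
    peak_n <- 0
    for (i in seq_along(region_kind)) {
      kind <- region_kind[i]
      npk <- if (kind == "SE") se_cluster_size else 1L
      amp_base <- if (kind == "SE") se_fold else 1
      region_start <- pos
      gene <- if (kind == "SE" && i <= n_tf) tf_genes[i] else
        sprintf("gene%04d", i)
      pk_ids <- character(npk)
      for (p in seq_len(npk)) {
        peak_n <- peak_n + 1
        pk_id <- sprintf("peak%05d", peak_n)
        pk_ids[p] <- pk_id
        amp <- amp_base * rlnorm(1, 0, typical_log_sd)
        peaks[[peak_n]] <- tibble(chrom = "chr1", start = pos,
                                  end = pos + enh_width, name = pk_id,
                                  score = round(amp * 100), strand = ".",
                                  signal_value = amp, p_value = -1,
                                  q_value = -1, peak_offset = -1)
        signal[[peak_n]] <- tibble(chrom = "chr1", start = pos,
                                   end = pos + enh_width, value = amp)
        seqs[[pk_id]] <- random_dna(enh_width)
        pos <- pos + enh_width + if (p < npk) gap_within else 0
      }
      region_end <- pos
      tss[[i]] <- tibble(chrom = "chr1", start = region_end + tss_offset,
                         end = region_end + tss_offset + 1, name = gene,
                         score = 0, strand = "+")
      if (kind == "SE") {
        se_truth[[length(se_truth) + 1]] <-
          tibble(chrom = "chr1", start = region_start, end = region_end,
                 gene = gene, se_id = sprintf("se%03d", length(se_truth) + 1))
        constituents_of_se[[gene]] <- pk_ids
      }
      pos <- pos + spacing
    }
    peaks <- bind_rows(peaks); signal <- bind_rows(signal)
    tss <- bind_rows(tss); se_truth <- bind_rows(se_truth)
    if (nrow(peaks) > 0 &&
        any(peaks$start[-1] < head(peaks$end, -1))) {
      stopf("internal: overlapping planted regions")  # layout is sequential
    }

    # plant motif occurrences -> known regulatory graph
    edges <- tibble(from = character(), to = character())
    plant <- function(tf, target_gene) {
      for (pk in constituents_of_se[[target_gene]]) {
        s <- seqs[[pk]]
        off <- 50 + (match(tf, tf_genes) - 1) * (motif_length + 8)
        substr(s, off, off + motif_length - 1) <- consensus[[tf]]
        seqs[[pk]] <<- s
      }
      edges <<- bind_rows(edges, tibble(from = tf, to = target_gene))
    }
    if (n_se > 0 && n_tf > 0) {
      for (g in se_truth$gene) plant(tf_genes[1], g)      # hub: everywhere
      if (n_tf >= 4) {
        for (a in tf_genes[2:4]) for (b in tf_genes[2:4]) plant(a, b)
      }
      if (n_tf >= 6) plant(tf_genes[5], tf_genes[6])
    }
    edges <- distinct(edges)

    truth <- list(
      planted_se_regions = se_truth,
      typical_peaks = peaks$name[!peaks$name %in%
                                   unlist(constituents_of_se)],
      planted_network = list(
        edges = edges,
        hub = if (n_tf > 0) tf_genes[1] else character(),
        circuit = if (n_tf >= 4) tf_genes[2:4] else character()),
      tf_genes = tf_genes,
      consensus = as.list(consensus),
      se_constituents = constituents_of_se,
      seeds = list(epigenome = seed))
    list(peaks = peaks, signal = signal, tss = tss, pwms = pwms,
         sequences = unlist(seqs), truth = truth)
  })
}
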