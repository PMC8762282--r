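#' Generate ortholog-linked synthetic expression data with planted truth
#'
#' Emulates the integrated multi-species granulosa/theca transcriptome:
#' stage-structured log-normal FPKM with species-aligned batch effects,
#' planted stage-marker blocks shared across species at corresponding
#' reference stages, and planted species-specific genes expressed only in
#' one species/compartment/stage block.
#'
#' Baseline log2-FPKM per ortholog group is drawn once from Normal(3, 2)
#' and shared across species, so cross-species stage correlations are
#' driven by the planted marker blocks on top of a common baseline.
#' Batch effects are additive per-gene, per-batch offsets on the log2
#' scale with one batch per species (the integrated public datasets come
#' one per study, so batch and species are confounded by design).
#'
#' @param n_genes number of ortholog groups.
#' @param species character vector of species codes; the first is the
#'   designated reference/query species for planted specific genes unless
#'   `specific_species` says otherwise.
#' @param stage_map named list, one integer vector per species giving the
#'   planted reference-stage index of each of its stages (non-decreasing).
#' @param compartments compartments to simulate (`"GC"`, `"TC"`).
#' @param n_reps replicates per species/compartment/stage (>= 2).
#' @param effect_fold fold-change of planted marker/specific blocks (> 1,
#'   or exactly 1 for a null fixture).
#' @param batch_sd SD (log2 units) of additive per-batch gene offsets.
#' @param gene_sd replicate-level biological noise SD (log2 units).
#' @param markers_per_stage planted marker genes per compartment and
#'   reference stage.
#' @param n_specific number of planted species-specific genes (confined
#'   to `specific_species`/`specific_compartment`/`specific_stage`).
#' @param specific_species,specific_compartment,specific_stage where the
#'   specific block lives; `specific_stage` indexes the species' own
#'   stage list.
#' @param n_specific_tc how many of the specific genes are additionally
#'   planted in the TC compartment at the same stage (these must be
#'   excluded by the species-specific gene extraction downstream).
#' @param seed integer RNG seed; regeneration with the same seed is
#'   identical.
#'
#' @return A list with `esets` (named list of per-species
#'   [follicle_expr]), `orthologs` (long tibble), and `truth` (planted
#'   stage map, marker blocks, specific genes, seeds).
#' @export
generate_expression <- function(n_genes = 500,
                                species = c("gal", "hsa", "bta"),
                                stage_map = NULL,
                                compartments = c("GC", "TC"),
                                n_reps = 3,
                                effect_fold = 16,
                                batch_sd = 1,
                                gene_sd = 0.2,
                                markers_per_stage = 30,
                                n_specific = 40,
                                specific_species = species[1],
                                specific_compartment = "GC",
                                specific_stage = 2,
                                n_specific_tc = 1,
                                seed = 1) {
  assert_count(n_genes, "n_genes", positive = TRUE)
  assert_count(n_reps, "n_reps", positive = TRUE)
  if (n_reps < 2) stopf("n_reps must be >= 2")
  if (!is.numeric(effect_fold) || effect_fold < 1) {
    stopf("effect_fold must be >= 1")
  }
  if (batch_sd < 0 || gene_sd < 0) stopf("SDs must be non-negative")
  if (is.null(stage_map)) {
    stage_map <- setNames(rep(list(1:3), length(species)), species)
  }
  stage_map <- lapply(stage_map, as.integer)
  if (any(vapply(stage_map, function(s) any(diff(s) < 0), logical(1)))) {
    stopf("stage_map entries must be non-decreasing")
  }
  n_ref_stages <- max(unlist(stage_map))
  withr::with_seed(seed, {
    groups <- sprintf("og%05d", seq_len(n_genes))
    orthologs <- tidyr::expand_grid(group_id = groups, species = species) %>%
      mutate(gene_id = paste(.data$species, .data$group_id, sep = "_"))

    # gene pools: specific genes first, then marker blocks, then background
    need <- n_specific + markers_per_stage * n_ref_stages * length(compartments)
    if (need > n_genes) stopf("n_genes too small for the planted blocks")
    specific_idx <- seq_len(n_specific)
    marker_idx <- list()
    nxt <- n_specific + 1
    for (cc in compartments) {
      for (r in seq_len(n_ref_stages)) {
        marker_idx[[paste(cc, r, sep = ".")]] <-
          seq(nxt, length.out = markers_per_stage)
        nxt <- nxt + markers_per_stage
      }
    }

    mu <- rnorm(n_genes, mean = 3, sd = 2)
    # off state of species-specific genes: detectable background well below
    # the expressed threshold; absence does not respond to batch
    mu_off <- -3
    mu[specific_idx] <- mu_off
    shift <- log2(effect_fold)

    esets <- list()
    for (sp in species) {
      stages <- stage_map[[sp]]
      n_st <- length(stages)
      samp <- tidyr::expand_grid(compartment = compartments,
                                 stage_idx = seq_len(n_st),
                                 replicate = seq_len(n_reps)) %>%
        mutate(species = sp,
               stage = paste0("s", .data$stage_idx),
               stage_order = .data$stage_idx,
               batch = sp,
               sample_id = paste(sp, .data$compartment, .data$stage,
                                 paste0("r", .data$replicate), sep = "_"))
      batch_offset <- if (batch_sd > 0) rnorm(n_genes, 0, batch_sd) else
        numeric(n_genes)
      vals <- matrix(0, n_genes, nrow(samp),
                     dimnames = list(
                       orthologs$gene_id[orthologs$species == sp][
                         match(groups,
                               orthologs$group_id[orthologs$species == sp])],
                       samp$sample_id))
      for (j in seq_len(nrow(samp))) {
        cc <- samp$compartment[j]
        r_stage <- stages[samp$stage_idx[j]]
        m <- mu + batch_offset + rnorm(n_genes, 0, gene_sd)
        if (n_specific > 0) {
          m[specific_idx] <- mu_off + rnorm(n_specific, 0, gene_sd)
        }
        if (effect_fold > 1) {
          m[marker_idx[[paste(cc, r_stage, sep = ".")]]] <-
            m[marker_idx[[paste(cc, r_stage, sep = ".")]]] + shift
        }
        on_here <- sp == specific_species &&
          samp$stage_idx[j] == specific_stage &&
          (cc == specific_compartment ||
             (cc == "TC" && n_specific_tc > 0))
        if (on_here && n_specific > 0) {
          idx <- if (cc == specific_compartment) specific_idx else
            specific_idx[seq_len(n_specific_tc)]
          m[idx] <- 3 + shift + rnorm(length(idx), 0, gene_sd)
        }
        vals[, j] <- 2^m
      }
      esets[[sp]] <- follicle_expr(vals, samp[, c(
        "sample_id", "species", "compartment", "stage", "stage_order",
        "replicate", "batch")])
    }

    sp_genes <- orthologs$gene_id[orthologs$species == specific_species]
    names(sp_genes) <- orthologs$group_id[orthologs$species == specific_species]
    truth <- list(
      planted_stage_map = stage_map,
      marker_blocks = lapply(marker_idx, function(i) groups[i]),
      planted_specific_groups = groups[specific_idx],
      planted_specific_genes = unname(sp_genes[groups[specific_idx]]),
      planted_specific_tc_genes =
        unname(sp_genes[groups[specific_idx[seq_len(n_specific_tc)]]]),
      specific_species = specific_species,
      specific_compartment = specific_compartment,
      specific_stage = specific_stage,
      seeds = list(expression = seed))
    list(esets = esets, orthologs = orthologs, truth = truth)
  })
}

#' Generate a one-to-one ortholog table
#'
#' @param n_genes number of ortholog groups.
#' @param species species codes.
#' @param seed RNG seed (kept for interface symmetry; the table is
#'   deterministic).
#' @return Long tibble `group_id, species, gene_id`; every gene appears
#'   in exactly one group.
#' @export
generate_orthologs <- function(n_genes = 500,
                               species = c("gal", "hsa", "bta"),
                               seed = 1) {
  groups <- sprintf("og%05d", seq_len(n_genes))
  tidyr::expand_grid(group_id = groups, species = species) %>%
    mutate(gene_id = paste(.data$species, .data$group_id, sep = "_"))
}

#' Generate a GMT-style annotation with planted enriched terms
#'
#' Planted terms draw their members from `planted_genes` only, so that a
#' query set containing the planted genes recovers them at the top of the
#' enrichment ranking; background terms are random draws from `genes`.
#'
#' @param genes background gene universe (IDs).
#' @param planted_genes genes to spread over the planted terms.
#' @param n_planted_terms,planted_term_size planted term count and size.
#' @param n_background_terms,background_term_size background term count
#'   and size.
#' @param seed RNG seed.
#' @return List with `annotation` (tibble `term, gene`) and `truth`
#'   (planted term IDs and their members).
#' @export
generate_annotation <- function(genes, planted_genes = character(),
                                n_planted_terms = 10,
                                planted_term_size = 12,
                                n_background_terms = 40,
                                background_term_size = 15,
                                seed = 1) {
  withr::with_seed(seed, {
    planted <- list()
    if (length(planted_genes) > 0 && n_planted_terms > 0) {
      size <- min(planted_term_size, length(planted_genes))
      for (i in seq_len(n_planted_terms)) {
        planted[[sprintf("BP_planted_%02d", i)]] <-
          sample(planted_genes, size)
      }
      # guarantee coverage: every planted gene sits in at least one term
      covered <- unique(unlist(planted))
      left_over <- setdiff(planted_genes, covered)
      if (length(left_over) > 0) {
        k <- n_planted_terms
        for (g in left_over) {
          slot <- (match(g, planted_genes) %% k) + 1
          planted[[slot]] <- c(planted[[slot]], g)
        }
      }
    }
    background <- list()
    for (i in seq_len(n_background_terms)) {
      background[[sprintf("BP_background_%02d", i)]] <-
        sample(genes, min(background_term_size, length(genes)))
    }
    all_terms <- c(planted, background)
    annotation <- purrr::imap_dfr(all_terms, function(gs, nm) {
      tibble(term = nm, gene = gs)
    })
    list(annotation = annotation,
         truth = list(planted_terms = names(planted),
                      planted_members = planted,
                      seeds = list(annotation = seed)))
  })
}
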