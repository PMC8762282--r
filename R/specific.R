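#' Cross-species homology percentage of stage gene sets
#'
#' Maps each species' marker set to ortholog-group IDs and reports
#' `100 * |intersection| / |union|` across species — the fraction of
#' follicle-development-related genes at a stage that are homologous
#' between the compared species.
#'
#' @param sets named list (per species) of gene-ID vectors.
#' @param orthologs long tibble `group_id, species, gene_id`.
#' @return Percentage, or `NA_real_` on an empty union.
#' @export
homology_overlap <- function(sets, orthologs) {
  if (length(sets) < 2) stopf("need sets for >= 2 species")
  orthologs <- as_tibble(orthologs)
  groups <- purrr::imap(sets, function(genes, sp) {
    tab <- orthologs[orthologs$species == sp, ]
    unique(tab$group_id[tab$gene_id %in% genes])
  })
  un <- unique(unlist(groups))
  if (length(un) == 0) return(NA_real_)
  inter <- Reduce(intersect, groups)
  100 * length(inter) / length(un)
}

#' Ectopically expressed ortholog groups
#'
#' An ortholog group is ectopically expressed at a stage when its
#' compartment of expression (granulosa-only vs theca-only, judged from
#' the stage marker sets) differs between the query species and at
#' least one other species. Groups appearing in both compartments in
#' any species are excluded.
#'
#' @param sets_by_species named list (per species) of lists with `GC`
#'   and `TC` gene-ID vectors for one stage.
#' @param orthologs long tibble `group_id, species, gene_id`.
#' @param query query species name (default first).
#' @return Tibble `group_id, query_class, other_species, other_class`
#'   with one row per ectopic group/species pair.
#' @export
ectopic_genes <- function(sets_by_species, orthologs,
                          query = names(sets_by_species)[1]) {
  if (length(sets_by_species) < 2) stopf("need >= 2 species")
  orthologs <- as_tibble(orthologs)
  class_of <- purrr::imap(sets_by_species, function(sets, sp) {
    tab <- orthologs[orthologs$species == sp, ]
    gc <- unique(tab$group_id[tab$gene_id %in% sets$GC])
    tc <- unique(tab$group_id[tab$gene_id %in% sets$TC])
    both <- intersect(gc, tc)
    tibble(group_id = c(setdiff(gc, tc), setdiff(tc, gc), both),
           class = c(rep("GC", length(setdiff(gc, tc))),
                     rep("TC", length(setdiff(tc, gc))),
                     rep("both", length(both))),
           species = sp)
  }) %>% bind_rows()
  excluded <- unique(class_of$group_id[class_of$class == "both"])
  single <- class_of %>% filter(!.data$group_id %in% excluded)
  q <- single %>% filter(.data$species == query) %>%
    select("group_id", query_class = "class")
  o <- single %>% filter(.data$species != query) %>%
    select("group_id", other_species = "species", other_class = "class")
  inner_join(q, o, by = "group_id") %>%
    filter(.data$query_class != .data$other_class) %>%
    arrange(.data$group_id, .data$other_species)
}

#' Extract species-specific follicle-development genes
#'
#' Implements the funnel from candidate biological processes to a final
#' species-specific gene set: take the top `top_k` terms of the target
#' compartment's enrichment (ordered by p), keep those present only in
#' that compartment (not significant in the other compartment's
#' enrichment at `alpha`), pool the query genes annotated to them as
#' candidates, and keep the candidates that are members of at least one
#' target-compartment stage set and of no other-compartment stage set.
#'
#' @param target_enrich [go_enrich()] table for the target compartment
#'   (e.g. granulosa cells at the differentiated stage).
#' @param other_enrich [go_enrich()] table for the other compartment.
#' @param annotation long tibble `term, gene`.
#' @param target_sets tibble from [stage_markers()] for the target
#'   compartment (any stage).
#' @param other_sets tibble from [stage_markers()] for the other
#'   compartment.
#' @param top_k how many top terms to consider (default 10).
#' @param alpha significance threshold used for "present" in the other
#'   compartment.
#' @return List with `top_terms`, `kept_terms` (target-only terms),
#'   `candidates`, and `spgs` (the final specific gene set).
#' @export
extract_spgs <- function(target_enrich, other_enrich, annotation,
                         target_sets, other_sets, top_k = 10,
                         alpha = 0.05) {
  top_terms <- head(target_enrich$term, top_k)
  other_present <- other_enrich$term[other_enrich$padj <= alpha]
  kept <- setdiff(top_terms, other_present)
  annotation <- as_tibble(annotation)
  candidates <- unique(annotation$gene[annotation$term %in% kept])
  in_target <- unique(target_sets$gene_id)
  in_other <- unique(other_sets$gene_id)
  spgs <- setdiff(intersect(candidates, in_target), in_other)
  list(top_terms = top_terms, kept_terms = kept,
       candidates = sort(candidates), spgs = sort(spgs))
}
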