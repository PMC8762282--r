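#' Write a complete synthetic fixture bundle to disk
#'
#' Generates every pipeline input with planted ground truth — per-species
#' expression and metadata TSVs, ortholog table, GMT annotation, peaks
#' (narrowPeak), signal (bedGraph), TSS (BED6), PWMs, SE constituent
#' FASTA, MAF alignment, query-interval BED, clade list — plus
#' `truth.json` and a `config.yaml` pointing at all of them. All
#' generators are seeded from `seed`, so regeneration is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; per-generator child seeds derive from it.
#' @param n_genes,species,n_reps,effect_fold,batch_sd forwarded to
#'   [generate_expression()].
#' @param n_enh,n_se forwarded to [generate_epigenome()].
#' @param n_species_aln forwarded to [generate_alignment_blocks()].
#' @return The config list, invisibly; files land under `dir`.
#' @export
write_fixture_bundle <- function(dir, seed = 1, n_genes = 500,
                                 species = c("gal", "hsa", "bta"),
                                 n_reps = 3, effect_fold = 16,
                                 batch_sd = 1, n_enh = 400, n_se = 20,
                                 n_species_aln = 77) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  ex <- generate_expression(n_genes = n_genes, species = species,
                            n_reps = n_reps, effect_fold = effect_fold,
                            batch_sd = batch_sd,
                            seed = child_seed(seed, 11))
  for (sp in species) {
    write_expr_tsv(ex$esets[[sp]], p(paste0("expr_", sp, ".tsv")))
    write_sample_meta(ex$esets[[sp]]$sample_meta,
                      p(paste0("meta_", sp, ".tsv")))
  }
  write_ortholog_table(ex$orthologs, p("orthologs.tsv"))

  target <- ex$truth$specific_species
  ann <- generate_annotation(
    genes = ex$orthologs$gene_id[ex$orthologs$species == target],
    planted_genes = ex$truth$planted_specific_genes,
    seed = child_seed(seed, 13))
  write_gmt(ann$annotation, p("annotation.gmt"))

  ep <- generate_epigenome(n_enh = n_enh, n_se = n_se,
                           seed = child_seed(seed, 17))
  write_narrowpeak(ep$peaks, p("peaks.narrowPeak"))
  write_bedgraph(ep$signal, p("signal.bedGraph"))
  write_bed6(ep$tss, p("tss.bed"))
  write_pwms(ep$pwms, p("motifs.pwm"))
  write_fasta(ep$sequences, p("constituents.fa"))

  al <- generate_alignment_blocks(n_species = n_species_aln,
                                  seed = child_seed(seed, 19))
  write_maf(al$blocks, p("alignment.maf"))
  write_bed6(al$intervals, p("intervals.bed"))
  write_lines(al$truth$clade, p("clade.txt"))

  truth <- list(expression = ex$truth, annotation = ann$truth,
                epigenome = list(
                  planted_se_regions = ep$truth$planted_se_regions,
                  planted_edges = ep$truth$planted_network$edges,
                  hub = ep$truth$planted_network$hub,
                  circuit = ep$truth$planted_network$circuit,
                  tf_genes = ep$truth$tf_genes,
                  se_constituents = ep$truth$se_constituents),
                alignment = list(
                  clade = al$truth$clade,
                  ref_species = al$truth$ref_species,
                  planted_verdicts = al$truth$planted_verdicts))
  write_truth_json(truth, p("truth.json"))

  config <- list(
    species = as.list(species),
    reference_species = species[length(species)],
    target_species = target,
    paths = list(
      expr = setNames(as.list(paste0("expr_", species, ".tsv")), species),
      meta = setNames(as.list(paste0("meta_", species, ".tsv")), species),
      orthologs = "orthologs.tsv", annotation = "annotation.gmt",
      peaks = "peaks.narrowPeak", signal = "signal.bedGraph",
      tss = "tss.bed", pwms = "motifs.pwm",
      constituents = "constituents.fa", maf = "alignment.maf",
      intervals = "intervals.bed", clade = "clade.txt",
      truth = "truth.json"),
    thresholds = list(min_fpkm = 1, padj = 0.05, gsea_p = 0.01,
                      stitch = 12500, tss_excl = 2500,
                      assign_window = 50000, hub_sd_multiplier = 1,
                      max_gap = 0.5, top_k_bps = 10,
                      motif_threshold = 0.8),
    specific_stage = ex$truth$specific_stage,
    seeds = list(master = seed, gsea = child_seed(seed, 23)))
  yaml::write_yaml(config, p("config.yaml"))
  invisible(config)
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    dir <- dirname(config)
    config <- yaml::read_yaml(config)
    config$dir <- dir
  }
  config
}

#' Run the full comparative pipeline from a config
#'
#' Executes the stages in dependency order — integrate, stage-align,
#' species-specific genes, super-enhancers, core regulatory circuitry,
#' conservation, gene-set enrichment — reading all inputs from the paths
#' in the config (as written by [write_fixture_bundle()]) and, when a
#' truth file is present, appending recovery metrics per stage. The
#' report is written as JSON next to the inputs and returned.
#'
#' @param config path to a `config.yaml` or an equivalent list with a
#'   `dir` entry.
#' @param report_path where to write the JSON report (default
#'   `report.json` in the config directory).
#' @return The report, a nested list, invisibly.
#' @export
run_pipeline <- function(config, report_path = NULL) {
  cfg <- read_config(config)
  dir <- cfg$dir %||% "."
  p <- function(x) file.path(dir, x)
  th <- cfg$thresholds
  for (path in unlist(cfg$paths)) {
    if (!file.exists(p(path))) stopf("input path does not exist: %s", p(path))
  }
  truth <- if (!is.null(cfg$paths$truth) && file.exists(p(cfg$paths$truth)))
    read_truth_json(p(cfg$paths$truth)) else NULL
  species <- unlist(cfg$species)
  report <- list()

  # --- integrate ---------------------------------------------------------
  esets <- setNames(lapply(species, function(sp) {
    read_expr_tsv(p(cfg$paths$expr[[sp]]), p(cfg$paths$meta[[sp]]))
  }), species)
  orthologs <- read_ortholog_table(p(cfg$paths$orthologs))
  integrated <- map_orthologs(esets, orthologs, min_fpkm = th$min_fpkm)
  corrected <- remove_batch(integrated)
  gc_cols <- corrected$sample_meta$compartment == "GC"
  z <- zscore_rows(corrected$values[, gc_cols, drop = FALSE])
  k <- 3
  cl <- cluster_samples(z, k)
  ref_meta <- corrected$sample_meta %>%
    filter(.data$species == cfg$reference_species, .data$compartment == "GC")
  cluster_names <- name_clusters(
    cl$labels, setNames(ref_meta$stage, ref_meta$sample_id),
    group_order = unique(ref_meta$stage[order(ref_meta$stage_order)]))
  report$integrate <- list(
    n_homologous_genes = nrow(integrated$values),
    n_samples = ncol(integrated$values),
    cluster_names = cluster_names$name)

  # --- stage alignment ---------------------------------------------------
  ref_series <- stage_series(corrected, cfg$reference_species, "GC")
  maps <- list(); correct <- 0; total <- 0
  for (sp in setdiff(species, cfg$reference_species)) {
    w <- align_stages(stage_series(corrected, sp, "GC"), ref_series)
    maps[[sp]] <- w$best_match
    if (!is.null(truth)) {
      planted <- unlist(truth$expression$planted_stage_map[[sp]])
      got <- match(w$best_match$reference_stage, ref_series$stages)
      correct <- correct + sum(got == planted)
      total <- total + length(planted)
    }
  }
  report$stagealign <- list(
    best_match = lapply(maps, function(m)
      setNames(as.list(m$reference_stage), m$query_stage)),
    stage_map_accuracy = if (total > 0) correct / total else NA)

  # --- species-specific genes -------------------------------------------
  target <- cfg$target_species
  markers <- list()
  for (sp in species) {
    for (cc in c("GC", "TC")) {
      markers[[paste(sp, cc, sep = ".")]] <-
        stage_markers(esets[[sp]], sp, cc, min_fpkm = th$min_fpkm,
                      alpha = th$padj)
    }
  }
  stage_labels <- sort(unique(markers[[paste(target, "GC", sep = ".")]]$stage))
  overlap_pct <- purrr::map_dbl(stage_labels, function(st) {
    sets <- setNames(lapply(species, function(sp) {
      m <- markers[[paste(sp, "GC", sep = ".")]]
      m$gene_id[m$stage == st]
    }), species)
    homology_overlap(sets, orthologs)
  })
  annotation <- read_gmt(p(cfg$paths$annotation))
  background <- orthologs$gene_id[orthologs$species == target]
  diff_stage <- stage_labels[cfg$specific_stage]
  enrich_of <- function(cc) {
    m <- markers[[paste(target, cc, sep = ".")]]
    q <- intersect(m$gene_id[m$stage == diff_stage], background)
    if (length(q) == 0) return(NULL)
    go_enrich(q, annotation, background)
  }
  gc_enrich <- enrich_of("GC"); tc_enrich <- enrich_of("TC")
  if (is.null(tc_enrich)) {
    tc_enrich <- tibble(term = character(), padj = numeric())
  }
  spg <- extract_spgs(gc_enrich, tc_enrich, annotation,
                      markers[[paste(target, "GC", sep = ".")]],
                      markers[[paste(target, "TC", sep = ".")]],
                      top_k = th$top_k_bps, alpha = th$padj)
  spg_metrics <- list()
  if (!is.null(truth)) {
    planted <- setdiff(unlist(truth$expression$planted_specific_genes),
                       unlist(truth$expression$planted_specific_tc_genes))
    tp <- length(intersect(spg$spgs, planted))
    spg_metrics <- list(
      spg_precision = if (length(spg$spgs) > 0) tp / length(spg$spgs)
        else NA,
      spg_recall = if (length(planted) > 0) tp / length(planted) else NA,
      tc_gene_excluded =
        !any(unlist(truth$expression$planted_specific_tc_genes) %in%
               spg$spgs))
  }
  report$specific <- c(list(
    gc_homology_percent = setNames(as.list(overlap_pct), stage_labels),
    n_spgs = length(spg$spgs), spgs = spg$spgs), spg_metrics)

  # --- super-enhancers ---------------------------------------------------
  peaks <- read_narrowpeak(p(cfg$paths$peaks))
  signal <- read_bedgraph(p(cfg$paths$signal))
  tss <- read_bed6(p(cfg$paths$tss))
  ses <- call_superenhancers(peaks, signal, tss,
                             stitch_dist = th$stitch,
                             tss_excl = th$tss_excl,
                             window = th$assign_window)
  se_metrics <- list()
  if (!is.null(truth)) {
    planted_se <- as_tibble(truth$epigenome$planted_se_regions)
    called <- ses %>% filter(.data$is_super)
    hit <- purrr::map_lgl(seq_len(nrow(called)), function(i) {
      any(planted_se$chrom == called$chrom[i] &
            planted_se$start < called$end[i] &
            planted_se$end > called$start[i])
    })
    recovered <- purrr::map_lgl(seq_len(nrow(planted_se)), function(i) {
      any(called$chrom == planted_se$chrom[i] &
            called$start < planted_se$end[i] &
            called$end > planted_se$start[i])
    })
    se_metrics <- list(
      se_precision = if (nrow(called) > 0) mean(hit) else NA,
      se_recall = if (nrow(planted_se) > 0) mean(recovered) else NA)
  }
  report$superenh <- c(list(n_regions = nrow(ses),
                            n_super = sum(ses$is_super)), se_metrics)

  # --- core regulatory circuitry ----------------------------------------
  pwms <- read_pwms(p(cfg$paths$pwms))
  sequences <- read_fasta(p(cfg$paths$constituents))
  seg <- ses %>% filter(.data$is_super) %>%
    select("region_id", "constituents", "genes") %>%
    unnest("genes") %>% rename(gene = "genes")
  tf_names <- vapply(pwms, function(x) x$tf, character(1))
  tf_constituents <- seg %>%
    filter(.data$gene %in% tf_names) %>%
    select(tf = "gene", "constituents") %>%
    unnest("constituents") %>% rename(peak_id = "constituents") %>%
    distinct()
  crc <- crc_analysis(sequences, tf_constituents, pwms,
                      threshold = th$motif_threshold,
                      hub_multiplier = th$hub_sd_multiplier)
  crc_metrics <- list()
  if (!is.null(truth)) {
    hub <- unlist(truth$epigenome$hub)
    oc <- setNames(crc$closeness$closeness_out, crc$closeness$tf)
    crc_metrics <- list(
      hub_recovered = hub %in% crc$closeness$tf[crc$closeness$hub] &&
        all(oc[hub] > oc[setdiff(names(oc), hub)]),
      hub_out_closeness = unname(oc[hub]),
      circuit_recovered = any(purrr::map_lgl(crc$circuits, function(cc)
        setequal(cc, unlist(truth$epigenome$circuit)))))
  }
  report$crc <- c(list(nodes = crc$nodes, n_edges = nrow(crc$edges),
                       hubs = crc$closeness$tf[crc$closeness$hub],
                       circuits = crc$circuits), crc_metrics)

  # --- conservation ------------------------------------------------------
  blocks <- read_maf(p(cfg$paths$maf))
  intervals <- read_bed6(p(cfg$paths$intervals))
  clade <- read_lines(p(cfg$paths$clade))
  ref_sp <- if (!is.null(truth)) truth$alignment$ref_species else
    blocks$species[1]
  verdicts <- conservation_verdicts(blocks, intervals, clade, ref_sp,
                                    max_gap = th$max_gap)
  cons_metrics <- list()
  if (!is.null(truth)) {
    want <- unlist(truth$alignment$planted_verdicts)
    cons_metrics <- list(clade_verdict_accuracy =
                           mean(verdicts$verdict == want[verdicts$name]))
  }
  report$conserv <- c(list(verdicts = setNames(as.list(verdicts$verdict),
                                               verdicts$name)),
                      cons_metrics)

  # --- gene-set enrichment of the specific genes ------------------------
  gsea_block <- list()
  if (length(spg$spgs) >= 2) {
    tgt_es <- esets[[target]]
    meta <- tgt_es$sample_meta
    gc_cols <- which(meta$compartment == "GC")
    sub <- subset_samples(tgt_es, gc_cols)
    stages <- sort(unique(sub$sample_meta$stage_order))
    sel <- which(sub$sample_meta$stage_order == stages[1])
    dif <- which(sub$sample_meta$stage_order ==
                   stages[min(cfg$specific_stage, length(stages))])
    de <- nb_wald_test(sub$values, sel, dif)
    ranked <- tibble(gene = de$gene_id, score = de$log2fc)
    gr <- gsea_p(ranked, spg$spgs, n_perm = 1000,
                 seed = cfg$seeds$gsea %||% 1)
    gsea_block <- list(gsea_es = gr$es, gsea_p = gr$p,
                       gsea_direction = gr$direction)
  }
  report$stats <- gsea_block

  report_path <- report_path %||% p("report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

#' One-command demo on a freshly generated fixture
#'
#' Writes a fixture bundle into `dir` and runs the whole pipeline on it.
#'
#' @param dir working directory (default a session temp dir).
#' @param seed master seed.
#' @return The pipeline report, invisibly.
#' @export
pipeline_demo <- function(dir = file.path(tempdir(), "folliclemap_demo"),
                          seed = 1) {
  write_fixture_bundle(dir, seed = seed)
  run_pipeline(file.path(dir, "config.yaml"))
}
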