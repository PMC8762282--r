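# Small expression sets built in code for unit tests.

toy_eset <- function(values, species = "gal", compartment = "GC",
                     stages = NULL, batch = species) {
  n <- ncol(values)
  if (is.null(stages)) stages <- rep("s1", n)
  meta <- tibble::tibble(
    sample_id = colnames(values), species = species,
    compartment = compartment, stage = stages,
    stage_order = as.integer(factor(stages, levels = unique(stages))),
    replicate = seq_len(n), batch = batch)
  follicle_expr(values, meta)
}

named_matrix <- function(data, genes, samples) {
  matrix(data, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# one shared small fixture bundle per test run (written once, reused)
fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "folliclemap_fixture")
      if (!file.exists(file.path(dir, "config.yaml"))) {
        write_fixture_bundle(dir, seed = 20240101)
      }
    }
    dir
  }
})
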