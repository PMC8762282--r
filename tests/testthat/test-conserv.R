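mini_blocks <- function() {
  # ref positions 100..109 in block 1, 110..114 in block 2; sp2 absent
  # from block 2; ref row of block 1 contains one gap column
  tibble::tibble(
    block_id = c(1, 1, 1, 2, 2),
    species = c("ref", "sp1", "sp2", "ref", "sp1"),
    chrom = c("chr1", "chrA", "chrB", "chr1", "chrA"),
    start = c(100, 0, 0, 110, 50),
    size = c(10, 9, 8, 5, 5),
    strand = "+",
    src_size = 1000,
    text = c("ACGTAC-GTAC",  # 10 ref bases, one gap column
             "ACGTACCGT-C",
             "AC--ACCGTAC",
             "GGGGG",
             "TTTT-"))
}

test_that("extract_homolog maps reference coordinates through gaps", {
  hom <- extract_homolog(mini_blocks(), list(chrom = "chr1", start = 102,
                                             end = 106), "ref")
  # ref columns for positions 102..105: "TA" then gap col excluded?
  # positions 102,103,104,105 -> columns 3,4,5,6 of block 1 text
  expect_equal(hom$sequences[["ref"]], "GTAC")
  expect_equal(nchar(hom$slices[["ref"]]), 4)
  expect_equal(hom$slices[["sp2"]], substr("AC--ACCGTAC", 3, 6))
})

test_that("spanning two blocks concatenates the covered reference bases", {
  hom <- extract_homolog(mini_blocks(), list(chrom = "chr1", start = 105,
                                             end = 113), "ref")
  expect_equal(nchar(hom$slices[["ref"]]), 8)  # 5 from b1 + 3 from b2
  expect_equal(hom$sequences[["ref"]], paste0("CGTAC", "GGG"))
  # sp2 absent from block 2 -> gap-filled there
  expect_equal(substr(hom$slices[["sp2"]], 6, 8), "---")
  # reference reconstruction invariant
  expect_false(grepl("-", hom$slices[["ref"]]))
})

test_that("uncovered reference bases become gap columns for others", {
  hom <- extract_homolog(mini_blocks(), list(chrom = "chr1", start = 113,
                                             end = 118), "ref")
  expect_equal(nchar(hom$slices[["ref"]]), 5)
  expect_equal(substr(hom$slices[["ref"]], 3, 5), "NNN")
  expect_equal(substr(hom$slices[["sp1"]], 3, 5), "---")
  expect_warning(
    empty <- extract_homolog(mini_blocks(),
                             list(chrom = "chr1", start = 500, end = 600),
                             "ref"),
    "no alignment block")
  expect_equal(empty$width, 0L)
})

test_that("gap_fraction counts gap characters per species", {
  expect_equal(gap_fraction(c(a = "AC--G", b = "-----", c = "ACGTA")),
               c(a = 0.4, b = 1, c = 0))
  expect_error(gap_fraction(c(a = "AC", b = "ACG")), "share")
})

test_that("reference gap fraction is identically zero on any interval", {
  g <- generate_alignment_blocks(n_species = 15, seed = 151)
  for (i in seq_len(nrow(g$intervals))) {
    iv <- g$intervals[i, ]
    mid <- list(chrom = iv$chrom, start = iv$start + 7,
                end = iv$end - 13)
    gf <- gap_fraction(extract_homolog(g$blocks, mid, "galGal")$slices)
    expect_equal(unname(gf["galGal"]), 0)
  }
})

test_that("clade_specificity applies the three-way verdict rule", {
  gf <- c(ref = 0, b1 = 0, b2 = 0.1, o1 = 1, o2 = 0.9)
  expect_equal(clade_specificity(gf, c("b1", "b2"), "ref"),
               "clade-specific")
  gf2 <- gf; gf2["o1"] <- 0.1
  expect_equal(clade_specificity(gf2, c("b1", "b2"), "ref"), "shared")
  gf3 <- c(ref = 0, b1 = 0.9, b2 = 0.8, o1 = 1)
  expect_equal(clade_specificity(gf3, c("b1", "b2"), "ref"),
               "not-conserved")
  expect_error(clade_specificity(gf, c("b1", "zz"), "ref"), "subset")
})

test_that("verdicts on the 77-species fixture equal the planted truth", {
  g <- generate_alignment_blocks(n_species = 77, gap_rate_in = 0.05,
                                 gap_rate_out = 0.6, seed = 157)
  vd <- conservation_verdicts(g$blocks, g$intervals, g$truth$clade,
                              "galGal")
  want <- unlist(g$truth$planted_verdicts)
  expect_identical(vd$verdict, unname(want[vd$name]))
  # clade and outgroup fractions separate cleanly at the fixture rates
  cons <- vd[vd$verdict == "clade-specific", ]$gap[[1]]
  clade <- setdiff(g$truth$clade, "galGal")
  out <- setdiff(names(cons), c(g$truth$clade, "galGal"))
  expect_true(all(cons[clade] < 0.2))
  expect_true(all(cons[out] > 0.2))
})

test_that("verdicts are invariant to splitting a block at any column", {
  g <- generate_alignment_blocks(n_species = 12, seed = 163)
  iv <- g$intervals[1, ]
  split_at <- 400  # columns
  b <- g$blocks
  target <- b[b$block_id == 1, ]
  left <- target; right <- target
  left$text <- substr(target$text, 1, split_at)
  left$size <- nchar(gsub("-", "", left$text))
  right$text <- substr(target$text, split_at + 1, nchar(target$text[1]))
  right$size <- nchar(gsub("-", "", right$text))
  right$block_id <- max(b$block_id) + 1
  right$start <- ifelse(target$species == "galGal",
                        target$start + split_at,
                        target$start + left$size)
  split_blocks <- dplyr::bind_rows(b[b$block_id != 1, ], left, right)
  v1 <- conservation_verdicts(b, g$intervals, g$truth$clade, "galGal")
  v2 <- conservation_verdicts(split_blocks, g$intervals, g$truth$clade,
                              "galGal")
  expect_identical(v1$verdict, v2$verdict)
  expect_equal(v1$gap[[1]], v2$gap[[1]])
})

test_that("binding profiles light up only where the motif is planted", {
  cs <- "ACGTACGTACGT"
  g <- generate_alignment_blocks(n_species = 10, motif_consensus = cs,
                                 seed = 167)
  pwm <- consensus_pwm("M1", "TFZ", cs)
  iv <- g$intervals[g$intervals$class == "clade_conserved", ][1, ]
  hom <- extract_homolog(g$blocks, iv, "galGal")
  bp <- binding_profile(hom$sequences, list(pwm), threshold = 0.9)
  clade <- c("galGal", g$truth$clade)
  expect_true(all(bp$hits[bp$species %in% clade] >= 1))
  # reference counts equal a direct scan of the reference sequence
  direct <- nrow(scan_motifs(hom$sequences[["galGal"]], pwm, 0.9))
  expect_equal(bp$hits[bp$species == "galGal"], direct)
})
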