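test_that("identity erosion hits its target as measured by the aligner", {
  panel <- crt_reference_panel()
  p <- panel[["crtI"]]
  expect_identical(mutate_to_identity(p, 1.0, seed = 1)$protein, p)
  m <- mutate_to_identity(p, 0.30, seed = 4)
  expect_gte(m$identity, 0.28)
  expect_lte(m$identity, 0.32)
  expect_equal(align_proteins(p, m$protein)$identity_fraction, m$identity)
  expect_error(mutate_to_identity(p, 0.10, seed = 1), "0.15")
  expect_error(mutate_to_identity(p, 1.2, seed = 1), "0.15")
  # deterministic per seed
  expect_identical(mutate_to_identity(p, 0.5, seed = 9)$protein,
                   mutate_to_identity(p, 0.5, seed = 9)$protein)
})

test_that("spec validation enforces template/genotype compatibility", {
  expect_error(synthetic_spec(template = "P5_YIG_together",
                              genotype = c("E", "B", "I", "Y", "Z")),
               "crtG")
  expect_error(synthetic_spec(yi = list(type = "overlap", bp = 9)), "1-8")
  expect_error(synthetic_spec(yi = list(type = "gap", bp = 5)), "6-25")
  expect_error(synthetic_spec(identity = 0.1), "identity")
  expect_error(synthetic_spec(gc = 0.9), "gc")
  expect_error(synthetic_spec(template = "scattered", log_between = TRUE,
                              genotype = c("E", "Y")),
               "log_between")
})

test_that("planted adjacency, strands and manifest match the emitted genome", {
  for (bp in c(1L, 8L)) {
    sp <- synthetic_spec(seed = 40 + bp, template = "P1_contiguous",
                         yi = list(type = "overlap", bp = bp))
    out <- build_synthetic_genome(sp)
    gm <- out$manifest$genes
    y <- gm[gm$symbol == "crtY", ]
    i <- gm[gm$symbol == "crtI", ]
    expect_equal(y$end - i$start, bp)
    # manifest coordinates equal the record's annotation exactly
    fx <- out$record$features
    for (k in seq_len(nrow(gm))) {
      row <- fx[fx$locus_tag == gm$locus_tag[k], ]
      expect_equal(row$start, gm$start[k])
      expect_equal(row$end, gm$end[k])
      expect_identical(row$strand, gm$strand[k])
    }
  }
  sp2 <- synthetic_spec(seed = 77, template = "P4_YIB_together",
                        yi = list(type = "gap", bp = 25L))
  gm2 <- build_synthetic_genome(sp2)$manifest$genes
  expect_equal(gm2$start[gm2$symbol == "crtI"] -
               gm2$end[gm2$symbol == "crtY"], 25L)
  # reverse-strand genes are reverse-complemented into the sequence
  sp3 <- synthetic_spec(seed = 5, template = "P1_contiguous")
  out3 <- build_synthetic_genome(sp3)
  g3 <- out3$manifest$genes[out3$manifest$genes$symbol == "crtG", ]
  expect_identical(g3$strand, "-")
  cds <- substr(out3$record$sequences[[1]], g3$start + 1L, g3$end)
  expect_identical(crtscan:::translate_cds(crtscan:::revcomp(cds)),
                   out3$record$features$protein[
                     out3$record$features$locus_tag == g3$locus_tag])
})

test_that("the same seed gives byte-identical files", {
  sp <- synthetic_spec(seed = 12, template = "P2_crtG_separated")
  d1 <- tempfile(); d2 <- tempfile()
  o1 <- build_synthetic_genome(sp, dir = d1)
  o2 <- build_synthetic_genome(sp, dir = d2)
  for (f in c("genbank", "gff3", "fasta", "manifest"))
    expect_identical(readLines(o1$paths[[f]]), readLines(o2$paths[[f]]))
  # and a different seed differs
  o3 <- build_synthetic_genome(synthetic_spec(seed = 13,
                                              template = "P2_crtG_separated"))
  expect_false(identical(o1$record$sequences, o3$record$sequences))
})

test_that("the cohort fixture loads, verifies, and derives genus", {
  fix <- build_cohort_fixture()
  expect_equal(nrow(fix), 41L)
  r13 <- fix[fix$serial == 13, ]
  expect_identical(r13$group, "III")
  expect_setequal(strsplit(r13$genotype, ",")[[1]],
                  c("E", "B", "I", "Y", "Z", "W", "X"))
  r41 <- fix[fix$serial == 41, ]
  expect_identical(r41$genotype, "E")
  expect_identical(r41$group, "IV")
  expect_identical(fix$genus[fix$serial == 5], "Sphingorhabdus")
})
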