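test_that("adjacency interval arithmetic matches the canonical cases", {
  a <- feat("u", 0L, 200L, "+")
  expect_mapequal_rel <- function(rel, ov, gap, co) {
    expect_equal(rel$overlap_bp, ov)
    expect_equal(rel$gap_bp, gap)
    expect_equal(rel$co_oriented, co)
  }
  # the canonical 4 bp translational-coupling overlap
  expect_mapequal_rel(adjacency(a, feat("d", 196L, 300L, "+")), 4L, 0L, TRUE)
  expect_mapequal_rel(adjacency(a, feat("d", 206L, 300L, "+")), 0L, 6L, TRUE)
  expect_mapequal_rel(adjacency(a, feat("d", 150L, 400L, "-")), 50L, 0L, FALSE)
  # order of arguments is immaterial: upstream is decided by coordinate
  rel <- adjacency(feat("d", 196L, 300L, "+"), a)
  expect_identical(rel$upstream_tag, "u")
  # different replicons: non-adjacent, no exception
  rel2 <- adjacency(a, feat("d", 0L, 90L, "+", replicon = "contig2"))
  expect_false(rel2$co_located)
  expect_true(is.na(rel2$overlap_bp))
})

test_that("overlap/gap arithmetic agrees with base-by-base counting", {
  set.seed(33)
  for (rep in 1:200) {
    s1 <- sample(0:400, 1); e1 <- s1 + sample(1:150, 1)
    s2 <- sample(0:400, 1); e2 <- s2 + sample(1:150, 1)
    if (s2 < s1) { tmp <- c(s1, e1); s1 <- s2; e1 <- e2; s2 <- tmp[1]; e2 <- tmp[2] }
    rel <- adjacency(feat("a", s1, e1), feat("b", s2, e2))
    oracle <- bp_overlap_oracle(s1, e1, s2, e2)
    expect_equal(rel$overlap_bp, oracle$overlap)
    if (rel$overlap_bp == 0L) expect_equal(rel$gap_bp, oracle$gap)
    expect_true(rel$overlap_bp == 0L || rel$gap_bp == 0L)
  }
})

test_that("locus construction splits on intervening count and span gap", {
  # crtY,I,B contiguous; crtG two decoys away opposite strand -> one locus
  rows <- list(feat("L1", 100L, 1000L, "+"), feat("L2", 996L, 2100L, "+"),
               feat("L3", 2200L, 3100L, "+"),
               feat("D1", 3200L, 3500L, "+"), feat("D2", 3600L, 3900L, "+"),
               feat("L4", 4000L, 4700L, "-"),
               feat("E1", 40000L, 40900L, "+"))
  rec <- tiny_genome(rows, length = 50000L)
  hits <- list(crtY = list(subject = "L1"), crtI = list(subject = "L2"),
               crtB = list(subject = "L3"), crtG = list(subject = "L4"),
               crtE = list(subject = "E1"))
  loci <- build_loci(hits, rec)
  expect_length(loci, 2L)
  expect_setequal(loci[[1]]$members$symbol, c("crtY", "crtI", "crtB", "crtG"))
  # crtE 35 kb away is a singleton locus
  expect_identical(loci[[2]]$members$symbol, "crtE")

  # 4 intervening CDS split a locus at the default threshold
  rows2 <- list(feat("A", 0L, 900L, "+"),
                feat("d1", 1000L, 1300L), feat("d2", 1400L, 1700L),
                feat("d3", 1800L, 2100L), feat("d4", 2200L, 2500L),
                feat("B", 2600L, 3500L, "+"))
  rec2 <- tiny_genome(rows2, length = 10000L)
  hits2 <- list(crtY = list(subject = "A"), crtI = list(subject = "B"))
  expect_length(build_loci(hits2, rec2), 2L)
  hits_none <- list(crtY = NULL)
  expect_length(build_loci(hits_none, rec2), 0L)
})

test_that("locus construction is invariant to hit order and translation", {
  rows <- list(feat("L1", 100L, 1000L, "+"), feat("L2", 996L, 2100L, "+"),
               feat("L3", 2200L, 3100L, "+"))
  rec <- tiny_genome(rows, length = 20000L)
  h1 <- list(crtY = list(subject = "L1"), crtI = list(subject = "L2"),
             crtB = list(subject = "L3"))
  h2 <- rev(h1)
  l1 <- build_loci(h1, rec)
  l2 <- build_loci(h2, rec)
  expect_identical(l1[[1]]$members$locus_tag, l2[[1]]$members$locus_tag)
  # translate all coordinates by a constant
  shift <- 5000L
  rows3 <- lapply(rows, function(r) { r$start <- r$start + shift
                                      r$end <- r$end + shift; r })
  rec3 <- tiny_genome(rows3, length = 20000L)
  l3 <- build_loci(h1, rec3)
  expect_identical(l3[[1]]$members$symbol, l1[[1]]$members$symbol)
  expect_equal(l3[[1]]$adjacencies[[1]]$overlap_bp,
               l1[[1]]$adjacencies[[1]]$overlap_bp)
})

test_that("architecture patterns follow membership, order and strand", {
  mk <- function(rows, hits) {
    rec <- tiny_genome(rows, length = 60000L)
    list(rec = rec, loci = build_loci(hits, rec), hits = hits)
  }
  # P4: Y,I,B contiguous co-oriented, G far away
  x <- mk(list(feat("a", 100L, 1000L, "+"), feat("b", 996L, 2100L, "+"),
               feat("c", 2200L, 3100L, "+"), feat("g", 30000L, 30700L, "-")),
          list(crtY = list(subject = "a"), crtI = list(subject = "b"),
               crtB = list(subject = "c"), crtG = list(subject = "g")))
  expect_identical(classify_architecture(x$loci, x$rec, x$hits)$pattern_label,
                   "P4_YIB_together")
  # P5: Y,I,G co-located, B apart
  x <- mk(list(feat("a", 100L, 1000L, "+"), feat("b", 996L, 2100L, "+"),
               feat("g", 2200L, 2900L, "+"), feat("c", 30000L, 30900L, "+")),
          list(crtY = list(subject = "a"), crtI = list(subject = "b"),
               crtG = list(subject = "g"), crtB = list(subject = "c")))
  expect_identical(classify_architecture(x$loci, x$rec, x$hits)$pattern_label,
                   "P5_YIG_together")
  # P3: Y/I away from B with mixed strands
  x <- mk(list(feat("a", 100L, 1000L, "-"), feat("b", 996L, 2100L, "-"),
               feat("c", 30000L, 30900L, "+"), feat("g", 45000L, 45700L, "-")),
          list(crtY = list(subject = "a"), crtI = list(subject = "b"),
               crtB = list(subject = "c"), crtG = list(subject = "g")))
  expect_identical(classify_architecture(x$loci, x$rec, x$hits)$pattern_label,
                   "P3_atypical")
  # single member -> partial
  x <- mk(list(feat("a", 100L, 1000L, "+")),
          list(crtY = list(subject = "a")))
  expect_identical(classify_architecture(x$loci, x$rec, x$hits)$pattern_label,
                   "partial")
})

test_that("crtY-crtI co-occurrence records overlaps, gaps and absences", {
  # strain lacking crtY
  rec <- tiny_genome(list(feat("i", 100L, 1000L, "+")))
  expect_false(yi_cooccurrence(list(crtI = list(subject = "i")),
                               rec)$both_present)
  # different contigs of a draft genome: co_located FALSE, overlap undefined
  rec2 <- genome_record("D", data.frame(replicon_id = c("c1", "c2"),
                                        length = c(5000L, 5000L)),
                        rbind(feat("y", 100L, 1000L, "+", replicon = "c1"),
                              feat("i", 100L, 1000L, "+", replicon = "c2")),
                        status = "draft")
  yi <- yi_cooccurrence(list(crtY = list(subject = "y"),
                             crtI = list(subject = "i")), rec2)
  expect_true(yi$both_present)
  expect_false(yi$co_located)
  expect_true(is.na(yi$overlap_bp))
})

test_that("cohort yi summary reports modal overlap and gap range", {
  # planted overlaps {4,4,1,8} and gaps {6,25}, by construction
  plant <- function(ov = NA, gap = NA) {
    b_start <- if (!is.na(ov)) 1000L - ov else 1000L + gap
    rec <- tiny_genome(list(feat("y", 100L, 1000L, "+"),
                            feat("i", b_start, b_start + 900L, "+")),
                       length = 10000L)
    yi_cooccurrence(list(crtY = list(subject = "y"),
                         crtI = list(subject = "i")), rec)
  }
  records <- rbind(plant(ov = 4), plant(ov = 4), plant(ov = 1),
                   plant(ov = 8), plant(gap = 6), plant(gap = 25))
  s <- yi_summary(records)
  expect_equal(s$n_both_present, 6L)
  expect_equal(s$n_overlapping, 4L)
  expect_equal(s$modal_overlap_bp, 4L)
  expect_equal(s$gap_range, c(6L, 25L))
})
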