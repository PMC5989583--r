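test_that("source coordinate conventions convert to half-open internals", {
  gbk <- tempfile(fileext = ".gbk")
  dna <- paste(rep("ATGGCTGCTTAA", 5), collapse = "")
  rec <- tiny_genome(list(
    feat("A1", 0L, 6L, "+", protein = "X"),
    feat("A2", 9L, 30L, "-", protein = "X")), length = 60L,
    sequences = c(chr = dna))
  writeLines(c(
    "LOCUS       chr              60 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  Test strain.",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..6",
    "                     /locus_tag=\"A1\"",
    "                     /translation=\"X\"",
    "     CDS             complement(10..30)",
    "                     /locus_tag=\"A2\"",
    "                     /translation=\"X\"",
    "     CDS             1..12",
    "                     /locus_tag=\"A3\"",
    "//"), gbk)
  expect_warning(parsed <- parse_genome(gbk), "skipping")
  fx <- parsed$features
  expect_equal(fx$start[fx$locus_tag == "A1"], 0L)
  expect_equal(fx$end[fx$locus_tag == "A1"], 6L)
  expect_equal(fx$strand[fx$locus_tag == "A1"], "+")
  expect_equal(fx$start[fx$locus_tag == "A2"], 9L)
  expect_equal(fx$end[fx$locus_tag == "A2"], 30L)
  expect_equal(fx$strand[fx$locus_tag == "A2"], "-")
  # A3 has no translation and the file has no ORIGIN -> skipped with warning
  expect_false("A3" %in% fx$locus_tag)
})

test_that("translation table 11 derives proteins when no annotation exists", {
  gbk <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       chr              12 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  T.",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..12",
    "                     /locus_tag=\"A1\"",
    "ORIGIN",
    "        1 atggctgctt aa",
    "//"), gbk)
  parsed <- parse_genome(gbk)
  expect_equal(parsed$features$protein, "MAA")
})

test_that("GenBank and GFF3 round-trips reproduce all feature fields", {
  dna <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
  # proteins consistent with the sequence so the GFF3 route can re-derive
  p1 <- crtscan:::translate_cds(substr(dna, 11, 100))
  p2 <- crtscan:::translate_cds(crtscan:::revcomp(substr(dna, 151, 300)))
  p3 <- crtscan:::translate_cds(substr(dna, 401, 475))
  rec <- tiny_genome(list(
    feat("B1", 10L, 100L, "+", p1),
    feat("B2", 150L, 300L, "-", p2, product = "weird; product=x"),
    feat("B3", 400L, 475L, "?", p3)),
    length = 600L, sequences = c(chr = dna), status = "draft")
  gbk <- tempfile(fileext = ".gbk")
  write_genome(rec, gbk, "genbank")
  back <- parse_genome(gbk)
  expect_identical(back$features, rec$features)
  expect_identical(back$sequences, rec$sequences)
  expect_identical(back$status, "draft")

  pre <- tempfile()
  write_genome(rec, pre, "gff3+fasta")
  back2 <- parse_genome(paste0(pre, ".gff3"))
  expect_identical(back2$features, rec$features)
  # unknown strand is serialised as '.' in the GFF3 dialect
  gff <- readLines(paste0(pre, ".gff3"))
  b3 <- grep("ID=B3", gff, value = TRUE)
  expect_identical(strsplit(b3, "\t")[[1]][7], ".")
  # write-parse-write is byte-stable
  pre2 <- tempfile()
  write_genome(back2, pre2, "gff3+fasta")
  expect_identical(readLines(paste0(pre2, ".gff3")), gff)
})

test_that("empty feature tables survive a round-trip", {
  rec <- genome_record("Empty", data.frame(replicon_id = "c1", length = 100L),
                       feat("x", 1, 2)[0, ],
                       sequences = c(c1 = strrep("ACGT", 25)))
  pre <- tempfile()
  write_genome(rec, pre, "gff3+fasta")
  back <- parse_genome(paste0(pre, ".gff3"))
  expect_equal(nrow(back$features), 0L)
})

test_that("coordinate round-trip is the identity on random valid features", {
  set.seed(42)
  dna <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  starts <- sort(sample(seq(0, 4500, by = 150), 10))
  rows <- lapply(seq_along(starts), function(i) {
    len <- sample(10:40, 1) * 3L
    s <- starts[i]
    strand <- sample(c("+", "-"), 1)
    cds <- substr(dna, s + 1, s + len)
    if (strand == "-") cds <- crtscan:::revcomp(cds)
    feat(sprintf("R%02d", i), s, s + len, strand,
         protein = crtscan:::translate_cds(cds))
  })
  rec <- tiny_genome(rows, length = 5000L, sequences = c(chr = dna))
  for (fmt in c("genbank", "gff3+fasta")) {
    path <- if (fmt == "genbank") tempfile(fileext = ".gbk") else tempfile()
    write_genome(rec, path, fmt)
    rt <- parse_genome(if (fmt == "genbank") path else paste0(path, ".gff3"))
    expect_identical(rt$features, rec$features, label = fmt)
  }
})

test_that("record validation rejects malformed input", {
  expect_error(tiny_genome(list(feat("z", 50L, 20L))), "start < end")
  expect_error(tiny_genome(list(feat("z", 0L, 20000L)), length = 100L),
               "beyond replicon bounds")
  expect_error(tiny_genome(list(feat("z", 0L, 9L), feat("z", 20L, 29L))),
               "unique")
  expect_error(parse_genome(tempfile()), "not found")
})

test_that("start-codon curation prefers ATG > GTG > TTG > CTG upstream", {
  # layout: ...ATG...GTG...[annotated CTG start]...  all in frame, no stops
  up <- "ATGGCTGTGGCA"            # ATG at 0, GTG at 6 (in frame)
  core <- "CTGGCAGCAGCATAA"       # annotated start at CTG
  dna <- paste0(strrep("C", 9), up, core, strrep("C", 10))
  s <- 9L + nchar(up)
  rec <- tiny_genome(list(
    feat("C1", s, s + nchar(core), "+",
         protein = crtscan:::translate_cds(core))),
    length = nchar(dna), sequences = c(chr = dna))
  cur <- curate_start_codons(rec, window = 12L)
  expect_equal(cur$features$start, 9L)  # jumped to the ATG, not the GTG
  expect_match(cur$features$protein, "^M")
  # annotated ATG is left alone
  rec2 <- tiny_genome(list(
    feat("C2", 9L, 9L + nchar(up) + nchar(core), "+",
         protein = crtscan:::translate_cds(paste0(up, core)))),
    length = nchar(dna), sequences = c(chr = dna))
  expect_equal(curate_start_codons(rec2)$features$start, 9L)
})
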