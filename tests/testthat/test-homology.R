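test_that("self-alignment and non-alignable pairs behave as expected", {
  a <- align_proteins("MKV", "MKV")
  expect_equal(a$identity_fraction, 1.0)
  expect_equal(a$alignment_length, 3L)
  # no positive-scoring path longer than a single cell for A vs C
  sub <- scoring22
  a2 <- align_proteins("AAAA", "CCCC")
  expect_lte(a2$raw_score, max(0, sub["A", "C"]))
  expect_error(align_proteins("", "MKV"), "empty")
  expect_error(align_proteins("MKB", "MKV"), "unknown residue")
  # X is tolerated and scored 0
  expect_silent(align_proteins("MXV", "MKV"))
})

test_that("local score matches exhaustive enumeration on a frozen example", {
  # value computed once with bf_local_score on these peptides
  expect_equal(align_proteins("PAWHEAE", "HEAGAWGHEE")$raw_score, 17L)
})

test_that("aligner equals the brute-force oracle on short peptides", {
  set.seed(101)
  # exhaustive over all pairs of length <= 2 over a 4-letter sub-alphabet
  alpha <- c("A", "C", "D", "W")
  short <- c(alpha, as.vector(outer(alpha, alpha, paste0)))
  for (qa in short) for (qb in short) {
    expect_equal(align_proteins(qa, qb)$raw_score,
                 bf_local_score(qa, qb, scoring22),
                 label = paste(qa, qb))
  }
  # random sample at lengths 3-6
  for (rep in 1:60) {
    qa <- random_peptide(sample(3:6, 1))
    qb <- random_peptide(sample(3:6, 1))
    expect_equal(align_proteins(qa, qb)$raw_score,
                 bf_local_score(qa, qb, scoring22),
                 label = paste(qa, qb))
  }
})

test_that("raw score is symmetric for a symmetric matrix", {
  set.seed(7)
  for (rep in 1:25) {
    qa <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G"),
                       sample(4:12, 1), replace = TRUE), collapse = "")
    qb <- paste(sample(c("H", "I", "L", "K", "M", "F", "P", "S"),
                       sample(4:12, 1), replace = TRUE), collapse = "")
    expect_equal(align_proteins(qa, qb)$raw_score,
                 align_proteins(qb, qa)$raw_score)
  }
})

test_that("bit score and E-value follow the Karlin-Altschul relations", {
  p <- alignment_params()
  # closed form checked independently: bit = (0.267*100 - ln 0.041)/ln 2
  ev <- evalue(100L, p, m = 300L, n = 1e6L)
  bit_expected <- (0.267 * 100 - log(0.041)) / log(2)
  expect_equal(ev$bit_score, bit_expected, tolerance = 1e-12)
  expect_equal(ev$e_value, 300 * 1e6 * 2^(-bit_expected), tolerance = 1e-12)
  # bit = log2(m*n)  =>  E = 1
  s_star <- (log2(300 * 1e6) * log(2) + log(p$K)) / p$lambda
  expect_equal(evalue(s_star, p, 300, 1e6)$e_value, 1, tolerance = 1e-9)
  # monotone decreasing in raw score, towards 0
  es <- vapply(seq(10, 600, by = 10),
               function(s) evalue(s, p, 300, 1e6)$e_value, 0)
  expect_true(all(diff(es) < 0))
  expect_lt(es[length(es)], 1e-40)
  expect_error(evalue(50, p, 0, 10), ">= 1")
})

test_that("orthologue calling applies the four criteria and best-hit rule", {
  panel <- crt_reference_panel()
  query <- panel[["crtZ"]]
  # subject identical to the query -> accepted with identity 1, ldiff 0
  rec <- tiny_genome(list(feat("S1", 100L, 100L + 3L * (nchar(query) + 1L),
                               protein = query)),
                     length = 5000L)
  hits <- call_orthologues(c(crtZ = query), rec)
  expect_true(hits$crtZ$accepted)
  expect_equal(hits$crtZ$alignment$identity_fraction, 1.0)
  expect_equal(hits$crtZ$length_difference, 0)

  # identity boundary: inclusive at the threshold, rejected just below
  m30 <- mutate_to_identity(query, 0.32, seed = 5)
  rec2 <- tiny_genome(list(feat("S2", 100L, 700L, protein = m30$protein)),
                      length = 5000L)
  h2 <- call_orthologues(c(crtZ = query), rec2,
                         orthology_criteria(min_identity = m30$identity))
  expect_true(h2$crtZ$accepted)
  h3 <- call_orthologues(c(crtZ = query), rec2,
                         orthology_criteria(min_identity = m30$identity +
                                              1e-9))
  expect_null(h3$crtZ)
  cand <- attr(call_orthologues(c(crtZ = query), rec2,
                                orthology_criteria(min_identity =
                                                     m30$identity + 1e-9),
                                all_candidates = TRUE), "candidates")
  expect_identical(cand$reasons[cand$subject == "S2"], "min_identity")

  # among accepted candidates the highest identity wins
  m55 <- mutate_to_identity(query, 0.55, seed = 6)$protein
  m62 <- mutate_to_identity(query, 0.62, seed = 7)$protein
  rec3 <- tiny_genome(list(feat("T1", 100L, 700L, protein = m55),
                           feat("T2", 2000L, 2600L, protein = m62)),
                      length = 5000L)
  h4 <- call_orthologues(c(crtZ = query), rec3)
  expect_identical(h4$crtZ$subject, "T2")

  # length-difference criterion is strict
  stub <- substr(query, 1, ceiling(nchar(query) * 0.79))
  rec4 <- tiny_genome(list(feat("U1", 100L, 700L, protein = stub)),
                      length = 5000L)
  c4 <- attr(call_orthologues(c(crtZ = query), rec4, all_candidates = TRUE),
             "candidates")
  expect_match(c4$reasons[1], "max_length_difference")

  expect_error(call_orthologues(character(0), rec), "empty query panel")
  empty <- tiny_genome(list(feat("x", 1, 10)[0, ]))
  expect_equal(call_orthologues(c(crtZ = query), empty), list(crtZ = NULL))
})

test_that("planted orthologues are recovered and random decoys rejected", {
  panel <- crt_reference_panel(c("crtE", "crtI", "crtZ"))
  for (seed in 1:20) {
    set.seed(seed)
    mut <- mutate_to_identity(panel[["crtI"]], 0.40, seed = seed)
    decoy <- paste(sample(names(crtscan:::AA_FREQ), 300, replace = TRUE,
                          prob = crtscan:::AA_FREQ), collapse = "")
    rec <- tiny_genome(list(feat("P1", 100L, 2000L, protein = mut$protein),
                            feat("D1", 3000L, 4000L, protein = decoy)),
                       length = 10000L)
    hits <- call_orthologues(panel, rec)
    expect_identical(hits$crtI$subject, "P1", label = paste("seed", seed))
    expect_null(hits$crtE)
    expect_null(hits$crtZ)
  }
})
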