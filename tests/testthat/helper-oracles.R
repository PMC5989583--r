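# Independent brute-force oracles used across the suite.

# Exhaustive global affine alignment score by enumerating every column
# sequence (gap run of length k costs open + k * ext).  `prev` is the column
# type to the right of the current one.
bf_global_affine <- function(a, b, sub, open, ext) {
  rec <- function(i, j, prev) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1, "m") + sub[a[i], b[j]])
    if (i > 0)
      best <- max(best, rec(i - 1, j, "x") - ext - if (prev != "x") open else 0)
    if (j > 0)
      best <- max(best, rec(i, j - 1, "y") - ext - if (prev != "y") open else 0)
    best
  }
  rec(length(a), length(b), "m")
}

# Brute-force local score: best over all substring pairings (empty = 0).
bf_local_score <- function(A, B, sub, open = 11, ext = 1) {
  a <- strsplit(A, "")[[1]]
  b <- strsplit(B, "")[[1]]
  best <- 0
  for (i1 in seq_along(a)) for (i2 in i1:length(a))
    for (j1 in seq_along(b)) for (j2 in j1:length(b))
      best <- max(best, bf_global_affine(a[i1:i2], b[j1:j2], sub, open, ext))
  best
}

# Sliding-window motif oracle built on base regex matching (independent of
# the package's position-wise matcher).
regex_motif_starts <- function(protein, pattern_txt) {
  rx <- gsub("\\(x\\)([0-9]+)", ".{\\1}", gsub("_", "", pattern_txt))
  rx <- gsub("x", ".", rx)
  m <- gregexpr(paste0("(?=", rx, ")"), protein, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Base-by-base interval overlap/gap oracle on half-open intervals.
bp_overlap_oracle <- function(s1, e1, s2, e2) {
  cells1 <- seq(s1, e1 - 1)
  cells2 <- seq(s2, e2 - 1)
  ov <- length(intersect(cells1, cells2))
  gap <- if (ov > 0) 0L else max(0L, max(s1, s2) - min(e1, e2))
  list(overlap = ov, gap = gap)
}

# Reachability oracle via igraph over the applicable-edge subgraph.
igraph_reachable <- function(enzymes, graph, precursors = c("IPP", "DMAPP")) {
  ok <- vapply(graph$enzymes, function(z) all(z %in% enzymes), TRUE)
  sub <- graph[ok, , drop = FALSE]
  edges <- rbind(cbind(sub$substrate, sub$product),
                 cbind(sub$product[sub$reversible],
                       sub$substrate[sub$reversible]))
  nodes <- unique(c(precursors, as.vector(edges)))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), vertices = nodes)
  reach <- unique(unlist(lapply(precursors, function(p)
    names(igraph::subcomponent(g, p, mode = "out")))))
  sort(reach)
}

scoring22 <- crtscan:::scoring_matrix("BLOSUM62")

random_peptide <- function(len, alphabet = c("A", "C", "D", "W"))
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
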