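#' Alignment parameters
#'
#' Scoring parameters for local protein alignment and for converting raw
#' scores to bit scores and E-values via the Karlin-Altschul relations.
#' Defaults are the published gapped BLOSUM62 / 11,1 constants
#' (lambda = 0.267, K = 0.041).  A gap of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param matrix Substitution matrix name; only `"BLOSUM62"` is bundled.
#' @param gap_open,gap_extend Positive integer gap penalties.
#' @param lambda,K Karlin-Altschul parameters (both > 0).
#' @return An object of class `AlignmentParams`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11L,
                             gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (gap_open <= 0 || gap_extend <= 0) stopf("gap penalties must be positive")
  if (lambda <= 0 || K <= 0) stopf("lambda and K must be positive")
  structure(list(matrix = matrix, values = scoring_matrix(matrix),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "AlignmentParams")
}

# BLOSUM62 over the 20 canonical residues plus X, with X scored 0 against
# everything (including itself).
scoring_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(name = "BLOSUM62") {
    if (!identical(name, "BLOSUM62"))
      stopf("unknown substitution matrix '%s'", name)
    if (is.null(cache$BLOSUM62)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[AA20, AA20]
      m <- rbind(cbind(m, X = 0L), X = 0L)
      storage.mode(m) <- "integer"
      cache$BLOSUM62 <- m
    }
    cache$BLOSUM62
  }
})

encode_protein <- function(x, alphabet) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stopf("unknown residue(s) in protein sequence: %s",
          paste(bad, collapse = ", "))
  }
  idx
}

#' Smith-Waterman local protein alignment
#'
#' Optimal local alignment with affine gap penalties.  Identity is the number
#' of identical columns divided by the total alignment length, gap columns
#' included in the denominator (the BLAST convention).  Traceback is
#' deterministic: ties are broken diagonal, then up, then left.
#'
#' @param query,subject Non-empty amino-acid strings over the 20-letter
#'   alphabet; `X` is allowed and scores 0 against everything.
#' @param params An [alignment_params()] object.
#' @return An object of class `ProteinAlignment` with elements `raw_score`,
#'   `bit_score`, `e_value` (computed with m = query length, n = subject
#'   length), `identity_fraction`, `alignment_length`, and half-open
#'   `query_span` / `subject_span`.
#' @examples
#' aln <- align_proteins("MKV", "MKV")
#' aln$identity_fraction  # 1
#' @export
align_proteins <- function(query, subject, params = alignment_params()) {
  if (!nzchar(query) || !nzchar(subject)) stopf("empty protein sequence")
  alpha <- rownames(params$values)
  q <- encode_protein(query, alpha)
  s <- encode_protein(subject, alpha)
  res <- sw_align_cpp(q, s, params$values, params$gap_open, params$gap_extend)
  ev <- evalue(res$score, params, m = length(q), n = length(s))
  structure(list(
    raw_score = res$score,
    bit_score = ev$bit_score,
    e_value = ev$e_value,
    identity_fraction = if (res$alignment_length > 0)
      res$identities / res$alignment_length else 0,
    identities = res$identities,
    alignment_length = res$alignment_length,
    query_span = c(res$query_start, res$query_end),
    subject_span = c(res$subject_start, res$subject_end)),
    class = "ProteinAlignment")
}

#' Bit score and E-value from a raw alignment score
#'
#' Karlin-Altschul conversion: `bit = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^(-bit)`.
#'
#' @param raw_score Integer raw alignment score.
#' @param params An [alignment_params()] object supplying lambda and K.
#' @param m Query length (>= 1).
#' @param n Search-space length (>= 1); for a database search this is the
#'   summed subject length.
#' @return A list with `bit_score` and `e_value`.
#' @export
evalue <- function(raw_score, params = alignment_params(), m, n) {
  if (m < 1 || n < 1) stopf("search-space dimensions must be >= 1")
  bit <- (params$lambda * raw_score - log(params$K)) / log(2)
  list(bit_score = bit, e_value = as.numeric(m) * as.numeric(n) * 2^(-bit))
}

#' Orthology acceptance criteria
#'
#' The four composite criteria used to accept a candidate orthologue:
#' identity of at least `min_identity` (inclusive), length difference
#' strictly below `max_length_difference`, bit score of at least
#' `min_bit_score` (inclusive), and E-value strictly below `max_e_value`.
#' Length difference is `|len(query) - len(subject)| / len(query)`.
#'
#' @param min_identity Minimum identity fraction, default 0.30.
#' @param max_length_difference Maximum relative length difference, 0.20.
#' @param min_bit_score Minimum bit score, default 50.
#' @param max_e_value Maximum E-value (exclusive), default 1e-10.
#' @return An object of class `OrthologyCriteria`.
#' @export
orthology_criteria <- function(min_identity = 0.30,
                               max_length_difference = 0.20,
                               min_bit_score = 50, max_e_value = 1e-10) {
  if (min_identity <= 0 || min_identity > 1)
    stopf("min_identity must be in (0, 1]")
  if (max_length_difference <= 0) stopf("max_length_difference must be > 0")
  if (min_bit_score < 0) stopf("min_bit_score must be >= 0")
  if (max_e_value <= 0) stopf("max_e_value must be > 0")
  structure(list(min_identity = min_identity,
                 max_length_difference = max_length_difference,
                 min_bit_score = min_bit_score,
                 max_e_value = max_e_value),
            class = "OrthologyCriteria")
}

check_criteria <- function(alignment, length_difference, criteria) {
  reasons <- character(0)
  if (alignment$identity_fraction < criteria$min_identity)
    reasons <- c(reasons, "min_identity")
  if (length_difference >= criteria$max_length_difference)
    reasons <- c(reasons, "max_length_difference")
  if (alignment$bit_score < criteria$min_bit_score)
    reasons <- c(reasons, "min_bit_score")
  if (alignment$e_value >= criteria$max_e_value)
    reasons <- c(reasons, "max_e_value")
  reasons
}

#' Identify crt orthologues in a genome
#'
#' Aligns every protein of the genome against each query of the reference
#' panel and applies the orthology criteria.  Among accepted candidates for
#' a query, the one with the highest identity fraction is returned (ties:
#' higher bit score, then lexicographically smallest locus tag).  The
#' E-value search space `n` is the summed proteome length, mirroring a
#' database search over one proteome.
#'
#' @param panel Named character vector of query proteins (names are gene
#'   symbols, e.g. `crtE`), or a `Biostrings::AAStringSet`.
#' @param genome A [GenomeRecord][genome_record()].
#' @param criteria An [orthology_criteria()] object.
#' @param params An [alignment_params()] object.
#' @param all_candidates If `TRUE`, attach the full per-candidate table
#'   (including rejected candidates with their rejection reasons) as
#'   attribute `"candidates"`.
#' @return A named list mapping each panel symbol to an `OrthologueHit`
#'   (fields `query_name`, `subject`, `alignment`, `length_difference`,
#'   `accepted`, `rejection_reasons`) or `NULL` when no candidate passes.
#' @export
call_orthologues <- function(panel, genome, criteria = orthology_criteria(),
                             params = alignment_params(),
                             all_candidates = FALSE) {
  if (methods::is(panel, "AAStringSet")) {
    panel <- stats::setNames(as.character(panel), names(panel))
  }
  if (length(panel) == 0L) stopf("empty query panel")
  if (is.null(names(panel)) || anyNA(names(panel)) || any(!nzchar(names(panel))))
    stopf("query panel entries must be named with gene symbols")
  if (anyDuplicated(names(panel)))
    stopf("query panel symbols must be unique")
  feats <- genome$features
  feats <- feats[nzchar(feats$protein), , drop = FALSE]
  hits <- stats::setNames(vector("list", length(panel)), names(panel))
  if (nrow(feats) == 0L) return(hits)
  nspace <- sum(nchar(feats$protein))
  cand_rows <- list()
  for (sym in names(panel)) {
    qseq <- panel[[sym]]
    best <- NULL
    for (k in seq_len(nrow(feats))) {
      sseq <- feats$protein[k]
      aln <- align_proteins(qseq, sseq, params)
      ev <- evalue(aln$raw_score, params, m = nchar(qseq), n = nspace)
      aln$bit_score <- ev$bit_score
      aln$e_value <- ev$e_value
      ldiff <- abs(nchar(qseq) - nchar(sseq)) / nchar(qseq)
      reasons <- check_criteria(aln, ldiff, criteria)
      if (all_candidates) {
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          query_name = sym, subject = feats$locus_tag[k],
          identity = aln$identity_fraction, bit_score = aln$bit_score,
          e_value = aln$e_value, length_difference = ldiff,
          accepted = length(reasons) == 0L,
          reasons = paste(reasons, collapse = ";"))
      }
      if (length(reasons) > 0L) next
      hit <- list(query_name = sym, subject = feats$locus_tag[k],
                  alignment = aln, length_difference = ldiff,
                  accepted = TRUE, rejection_reasons = character(0))
      class(hit) <- "OrthologueHit"
      if (is.null(best) ||
          hit$alignment$identity_fraction > best$alignment$identity_fraction ||
          (hit$alignment$identity_fraction == best$alignment$identity_fraction &&
           (hit$alignment$bit_score > best$alignment$bit_score ||
            (hit$alignment$bit_score == best$alignment$bit_score &&
             hit$subject < best$subject)))) {
        best <- hit
      }
    }
    hits[[sym]] <- best
  }
  if (all_candidates) {
    attr(hits, "candidates") <-
      do.call(rbind, cand_rows) %||%
      data.frame(query_name = character(0), subject = character(0),
                 identity = numeric(0), bit_score = numeric(0),
                 e_value = numeric(0), length_difference = numeric(0),
                 accepted = logical(0), reasons = character(0))
  }
  hits
}

#' Write a per-genome orthologue hit table
#'
#' @param hits Result of [call_orthologues()].
#' @param path Output TSV path.
#' @return Invisibly, the table written.
#' @export
write_hit_table <- function(hits, path) {
  rows <- lapply(names(hits), function(sym) {
    h <- hits[[sym]]
    if (is.null(h)) {
      data.frame(symbol = sym, locus_tag = NA_character_, identity = NA_real_,
                 bit_score = NA_real_, e_value = NA_real_,
                 length_difference = NA_real_, accepted = FALSE)
    } else {
      data.frame(symbol = sym, locus_tag = h$subject,
                 identity = round(h$alignment$identity_fraction, 4),
                 bit_score = round(h$alignment$bit_score, 2),
                 e_value = signif(h$alignment$e_value, 3),
                 length_difference = round(h$length_difference, 4),
                 accepted = TRUE)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$symbol), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
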