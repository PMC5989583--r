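#' Adjacency relation between two CDS features
#'
#' Pure interval arithmetic on half-open coordinates: the reading-frame
#' overlap is `max(0, min(end_u, end_d) - max(start_u, start_d))` and the
#' gap is `max(0, start_d - end_u)` for the feature pair ordered by start
#' coordinate.  Exactly one of overlap and gap is nonzero unless the ORFs
#' abut.  Features on different replicons are marked non-adjacent rather
#' than raising an error (draft-genome contigs never assert adjacency).
#'
#' @param a,b Single-row feature data frames (or lists) with `locus_tag`,
#'   `replicon_id`, `start`, `end`, `strand`.
#' @param genome Optional `GenomeRecord` used to count annotated CDS
#'   strictly between the two features.
#' @return A list of class `AdjacencyRelation`: `upstream_tag`,
#'   `downstream_tag` (ordered by start), `overlap_bp`, `gap_bp`,
#'   `co_oriented`, `intervening_orfs`, `co_located`.
#' @examples
#' a <- list(locus_tag = "u", replicon_id = "c", start = 0, end = 200, strand = "+")
#' b <- list(locus_tag = "d", replicon_id = "c", start = 196, end = 300, strand = "+")
#' adjacency(a, b)$overlap_bp  # 4
#' @export
adjacency <- function(a, b, genome = NULL) {
  if (!identical(a$replicon_id, b$replicon_id)) {
    return(structure(list(upstream_tag = a$locus_tag,
                          downstream_tag = b$locus_tag,
                          overlap_bp = NA_integer_, gap_bp = NA_integer_,
                          co_oriented = NA, intervening_orfs = NA_integer_,
                          co_located = FALSE),
                     class = "AdjacencyRelation"))
  }
  if (b$start < a$start) { tmp <- a; a <- b; b <- tmp }
  ov <- max(0L, min(a$end, b$end) - max(a$start, b$start))
  gap <- max(0L, b$start - a$end)
  inter <- NA_integer_
  if (!is.null(genome)) {
    fx <- genome$features
    inter <- sum(fx$replicon_id == a$replicon_id &
                 fx$start >= a$end & fx$end <= b$start &
                 !(fx$locus_tag %in% c(a$locus_tag, b$locus_tag)))
  }
  structure(list(upstream_tag = a$locus_tag, downstream_tag = b$locus_tag,
                 overlap_bp = as.integer(ov), gap_bp = as.integer(gap),
                 co_oriented = !is.na(a$strand) && !is.na(b$strand) &&
                   a$strand != "?" && b$strand != "?" &&
                   a$strand == b$strand,
                 intervening_orfs = as.integer(inter), co_located = TRUE),
            class = "AdjacencyRelation")
}

# features of accepted hits, with their symbols attached
hit_features <- function(hits, genome) {
  rows <- list()
  for (sym in names(hits)) {
    h <- hits[[sym]]
    if (is.null(h)) next
    k <- which(genome$features$locus_tag == h$subject)
    if (!length(k)) next
    f <- genome$features[k[1], , drop = FALSE]
    f$symbol <- sym
    rows[[length(rows) + 1L]] <- f
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(genome$features[0, , drop = FALSE])
  out[order(out$replicon_id, out$start), , drop = FALSE]
}

#' Group accepted crt hits into loci
#'
#' A locus is a maximal run of crt-hit features on one replicon in which
#' consecutive members are separated by at most `max_intervening` annotated
#' CDS and at most `max_span_gap_bp`.  Singleton loci are allowed.
#'
#' @param hits Result of [call_orthologues()] (accepted hits only are used).
#' @param genome The `GenomeRecord`.
#' @param max_intervening Maximum annotated CDS between consecutive
#'   members, default 3.
#' @param max_span_gap_bp Maximum bp between consecutive members, default
#'   10000.
#' @return A list of `LocusArchitecture` objects, each with `replicon_id`,
#'   `members` (data frame: symbol, locus_tag, start, end, strand) and
#'   `adjacencies` (list of [adjacency()] relations between consecutive
#'   members).
#' @export
build_loci <- function(hits, genome, max_intervening = 3L,
                       max_span_gap_bp = 10000L) {
  hf <- hit_features(hits, genome)
  if (!nrow(hf)) return(list())
  loci <- list()
  current <- hf[1, , drop = FALSE]
  flush <- function(members) {
    adj <- list()
    if (nrow(members) > 1L) {
      for (k in seq_len(nrow(members) - 1L))
        adj[[k]] <- adjacency(members[k, ], members[k + 1L, ], genome)
    }
    structure(list(replicon_id = members$replicon_id[1],
                   members = members[, c("symbol", "locus_tag",
                                         "replicon_id", "start", "end",
                                         "strand")],
                   adjacencies = adj),
              class = "LocusArchitecture")
  }
  for (k in seq_len(nrow(hf))[-1]) {
    prev <- current[nrow(current), ]
    rel <- adjacency(prev, hf[k, ], genome)
    joined <- isTRUE(rel$co_located) &&
      rel$intervening_orfs <= max_intervening &&
      (rel$overlap_bp > 0L || rel$gap_bp <= max_span_gap_bp)
    if (joined) {
      current <- rbind(current, hf[k, ])
    } else {
      loci[[length(loci) + 1L]] <- flush(current)
      current <- hf[k, , drop = FALSE]
    }
  }
  loci[[length(loci) + 1L]] <- flush(current)
  loci
}

locus_of <- function(loci, symbol) {
  for (i in seq_along(loci))
    if (symbol %in% loci[[i]]$members$symbol) return(i)
  NA_integer_
}

# CDS strictly between two members, not counting accepted accessory hits
# (LOG / DUF2141 travel inside crt loci without breaking contiguity)
intervening_non_accessory <- function(locus, i, genome, accessory_tags) {
  a <- locus$members[i, ]; b <- locus$members[i + 1L, ]
  fx <- genome$features
  between <- fx$replicon_id == a$replicon_id &
    fx$start >= a$end & fx$end <= b$start &
    !(fx$locus_tag %in% c(a$locus_tag, b$locus_tag))
  sum(between & !(fx$locus_tag %in% accessory_tags))
}

#' Classify the crt locus architecture
#'
#' Assigns one of the observed architecture patterns from the order, strand
#' and separation of the crtY/crtI/crtB/crtG members, and sets annotation
#' flags for the accessory features.  Accepted LOG / DUF2141 hits are not
#' counted as separating ORFs.
#'
#' Patterns: `P1_contiguous` - one locus holds crtB, crtI, crtY and crtG
#' with no separating ORFs; `P2_crtG_separated` - crtY/I/B contiguous with
#' crtG in the same locus but set apart by 1-3 ORFs; `P4_YIB_together` -
#' crtY/I/B co-located, crtG elsewhere (or absent with full-core genotype);
#' `P5_YIG_together` - crtY/I/G co-located, crtB elsewhere; `P3_atypical` -
#' crtY/I translocated away from crtB with mixed strands; `scattered` -
#' crt members present but matching no pattern; `partial` - fewer than two
#' of crtY/crtI/crtB present.
#'
#' @param loci Result of [build_loci()].
#' @param genome The `GenomeRecord`.
#' @param hits The orthologue hits (used for the accessory flags).
#' @return A list with `pattern_label` and logical `annotations`
#'   (`log_between_crtI_crtB`, `duf2141_adjacent_crtG`,
#'   `crtW_upstream_of_crtZ`, `crtW_downstream_of_crtZ`,
#'   `crtX_downstream_of_crtW`).
#' @export
classify_architecture <- function(loci, genome, hits = list()) {
  accessory_tags <- vapply(hits[intersect(names(hits), ACCESSORY_SYMBOLS)],
                           function(h) if (is.null(h)) NA_character_ else h$subject,
                           "")
  accessory_tags <- accessory_tags[!is.na(accessory_tags)]
  syms <- unlist(lapply(loci, function(l) l$members$symbol))
  have <- function(s) s %in% syms
  li <- list(Y = locus_of(loci, "crtY"), I = locus_of(loci, "crtI"),
             B = locus_of(loci, "crtB"), G = locus_of(loci, "crtG"))
  n_core <- sum(c(have("crtY"), have("crtI"), have("crtB")))

  pattern <- NULL
  if (n_core < 2L) {
    pattern <- "partial"
  } else {
    yi_together <- !is.na(li$Y) && identical(li$Y, li$I)
    yib_together <- yi_together && identical(li$Y, li$B)
    yig_together <- yi_together && !is.na(li$G) && identical(li$Y, li$G)
    if (yib_together && !is.na(li$G) && identical(li$G, li$Y)) {
      # all four share one locus: contiguous vs crtG set apart inside it
      locus <- loci[[li$Y]]
      n <- nrow(locus$members)
      seps <- vapply(seq_len(n - 1L), function(i)
        intervening_non_accessory(locus, i, genome, accessory_tags), 0)
      gpos <- which(locus$members$symbol == "crtG")[1]
      g_adj <- intersect(c(gpos - 1L, gpos), seq_len(n - 1L))
      other <- setdiff(seq_len(n - 1L), g_adj)
      if (all(seps == 0L)) {
        pattern <- "P1_contiguous"
      } else if (all(seps[other] == 0L) && all(seps[g_adj] <= 3L) &&
                 any(seps[g_adj] >= 1L)) {
        pattern <- "P2_crtG_separated"
      }
    } else if (yib_together) {
      pattern <- "P4_YIB_together"
    } else if (yig_together && have("crtB")) {
      pattern <- "P5_YIG_together"
    } else if (yi_together && have("crtB") && !identical(li$Y, li$B)) {
      ys <- loci[[li$Y]]$members$strand[loci[[li$Y]]$members$symbol == "crtY"]
      bs <- loci[[li$B]]$members$strand[loci[[li$B]]$members$symbol == "crtB"]
      if (ys != "?" && bs != "?" && ys != bs) pattern <- "P3_atypical"
    }
  }
  if (is.null(pattern)) {
    pattern <- "scattered"
    message("locus architecture matches no known pattern; labelled scattered")
  }

  ann <- c(log_between_crtI_crtB = FALSE, duf2141_adjacent_crtG = FALSE,
           crtW_upstream_of_crtZ = FALSE, crtW_downstream_of_crtZ = FALSE,
           crtX_downstream_of_crtW = FALSE)
  hf <- hit_features(hits, genome)
  feat_of <- function(sym) {
    k <- which(hf$symbol == sym)
    if (length(k)) hf[k[1], , drop = FALSE] else NULL
  }
  log_tag <- if (!is.null(hits$log)) hits$log$subject else NA
  fI <- feat_of("crtI"); fB <- feat_of("crtB")
  if (!is.na(log_tag) && !is.null(fI) && !is.null(fB) &&
      identical(fI$replicon_id, fB$replicon_id)) {
    lo <- min(fI$end, fB$end); hi <- max(fI$start, fB$start)
    fx <- genome$features
    between <- fx$locus_tag[fx$replicon_id == fI$replicon_id &
                            fx$start >= lo & fx$end <= hi &
                            !(fx$locus_tag %in% c(fI$locus_tag, fB$locus_tag))]
    ann["log_between_crtI_crtB"] <-
      length(between) == 1L && identical(between, log_tag)
  }
  duf_tag <- if (!is.null(hits$duf2141)) hits$duf2141$subject else NA
  fG <- feat_of("crtG")
  if (!is.na(duf_tag) && !is.null(fG)) {
    fD <- genome$features[genome$features$locus_tag == duf_tag, , drop = FALSE]
    rel <- adjacency(fG, fD, genome)
    ann["duf2141_adjacent_crtG"] <-
      isTRUE(rel$co_located) && rel$intervening_orfs == 0L
  }
  fW <- feat_of("crtW"); fZ <- feat_of("crtZ")
  if (!is.null(fW) && !is.null(fZ)) {
    rel <- adjacency(fW, fZ, genome)
    if (isTRUE(rel$co_located) && rel$intervening_orfs == 0L &&
        fZ$strand %in% c("+", "-")) {
      # upstream/downstream taken relative to crtZ's reading direction
      w_before <- fW$start < fZ$start
      w_upstream <- if (fZ$strand == "+") w_before else !w_before
      ann["crtW_upstream_of_crtZ"] <- w_upstream
      ann["crtW_downstream_of_crtZ"] <- !w_upstream
    }
  }
  fX <- feat_of("crtX")
  if (!is.null(fW) && !is.null(fX)) {
    rel <- adjacency(fW, fX, genome)
    if (isTRUE(rel$co_located) && rel$intervening_orfs == 0L &&
        fW$strand %in% c("+", "-")) {
      x_after <- fX$start > fW$start
      ann["crtX_downstream_of_crtW"] <-
        if (fW$strand == "+") x_after else !x_after
    }
  }
  list(pattern_label = pattern, annotations = ann)
}

#' crtY-crtI co-occurrence record
#'
#' Summarises, for one genome's hits and loci, whether crtY and crtI are
#' both present, co-located, co-oriented, and their reading-frame overlap
#' or separation in bp.
#'
#' @param hits Orthologue hits for the genome.
#' @param genome The `GenomeRecord`.
#' @param max_intervening,max_span_gap_bp Co-location thresholds as in
#'   [build_loci()].
#' @return A one-row data frame: `both_present`, `co_located`,
#'   `co_oriented`, `overlap_bp`, `gap_bp`.
#' @export
yi_cooccurrence <- function(hits, genome, max_intervening = 3L,
                            max_span_gap_bp = 10000L) {
  hf <- hit_features(hits, genome)
  fy <- hf[hf$symbol == "crtY", , drop = FALSE]
  fi <- hf[hf$symbol == "crtI", , drop = FALSE]
  if (!nrow(fy) || !nrow(fi))
    return(data.frame(both_present = FALSE, co_located = NA,
                      co_oriented = NA, overlap_bp = NA_integer_,
                      gap_bp = NA_integer_))
  rel <- adjacency(fy[1, ], fi[1, ], genome)
  co_loc <- isTRUE(rel$co_located) &&
    rel$intervening_orfs <= max_intervening &&
    (rel$overlap_bp > 0L || rel$gap_bp <= max_span_gap_bp)
  data.frame(both_present = TRUE, co_located = co_loc,
             co_oriented = if (co_loc) rel$co_oriented else NA,
             overlap_bp = if (co_loc) rel$overlap_bp else NA_integer_,
             gap_bp = if (co_loc) rel$gap_bp else NA_integer_)
}

#' Cohort-level crtY-crtI co-occurrence summary
#'
#' @param yi_records Data frame of per-strain [yi_cooccurrence()] rows.
#' @return A list: `n_both_present`, `n_co_located`, `n_overlapping`,
#'   `modal_overlap_bp`, `overlap_range`, `gap_range`.
#' @export
yi_summary <- function(yi_records) {
  ov <- yi_records$overlap_bp[!is.na(yi_records$overlap_bp) &
                              yi_records$overlap_bp > 0L]
  gp <- yi_records$gap_bp[!is.na(yi_records$gap_bp) &
                          yi_records$gap_bp > 0L]
  modal <- if (length(ov)) {
    tab <- table(ov)
    as.integer(names(tab)[which.max(tab)])
  } else NA_integer_
  list(n_both_present = sum(yi_records$both_present),
       n_co_located = sum(yi_records$co_located, na.rm = TRUE),
       n_overlapping = length(ov),
       modal_overlap_bp = modal,
       overlap_range = if (length(ov)) range(ov) else c(NA, NA),
       gap_range = if (length(gp)) range(gp) else c(NA, NA))
}

#' Plain-text locus diagram
#'
#' One line per locus, mirroring arrow maps of crt loci:
#' `crtY(+) -4bp- crtI(+) -gap 120bp- crtB(+)`.
#'
#' @param loci Result of [build_loci()].
#' @return Character vector, one element per locus.
#' @export
locus_diagram <- function(loci) {
  vapply(loci, function(l) {
    parts <- sprintf("%s(%s)", l$members$symbol, l$members$strand)
    if (length(l$adjacencies)) {
      seps <- vapply(l$adjacencies, function(a) {
        if (a$overlap_bp > 0L) sprintf("-overlap %dbp-", a$overlap_bp)
        else sprintf("-gap %dbp-", a$gap_bp)
      }, "")
      paste0(l$replicon_id, ": ",
             paste(parts, c(seps, ""), collapse = " "))
    } else paste0(l$replicon_id, ": ", parts)
  }, "")
}
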