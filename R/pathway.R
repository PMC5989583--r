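#' Carotenoid biosynthesis pathway graph
#'
#' The default graph encodes the presumptive carotenoid biosynthesis
#' pathways of Sphingomonadales: the central chain
#' DMAPP -> GGPP -> phytoene -> lycopene -> beta-carotene -> zeaxanthin,
#' with zeaxanthin as the branchpoint towards nostoxanthin (CrtG, via
#' caloxanthin), astaxanthin (CrtW, via adonixanthin) and erythroxanthin
#' (CrtW and CrtG); beta-carotene as the branchpoint towards canthaxanthin
#' (CrtW, via echinenone) and 2,2'-dihydroxycanthaxanthin (CrtW and CrtG);
#' glycosylation of astaxanthin by CrtX; and the cytokinin branch from
#' DMAPP (MiaA and LOG).  The IPP <-> DMAPP isomerisation (IDI) is the only
#' reversible edge.
#'
#' @param config Optional path to a TSV edge-list override/extension file
#'   with columns `substrate`, `product`, `enzymes` (comma-separated) and
#'   optionally `reversible` (TRUE/FALSE).  Rows are appended to the
#'   defaults; compounds and enzymes not previously known are declared by
#'   use.
#' @return An object of class `PathwayGraph`: a data frame of edges with
#'   columns `substrate`, `product`, `enzymes` (list column) and
#'   `reversible`.
#' @examples
#' nrow(load_pathway_graph())  # 16 default edges
#' @export
load_pathway_graph <- function(config = NULL) {
  e <- function(s, p, enz, rev = FALSE)
    data.frame(substrate = s, product = p,
               enzymes = I(list(enz)), reversible = rev)
  edges <- rbind(
    e("IPP", "DMAPP", "IDI", rev = TRUE),
    e("DMAPP", "GGPP", "CrtE"),
    e("GGPP", "phytoene", "CrtB"),
    e("phytoene", "lycopene", "CrtI"),
    e("lycopene", "beta-carotene", "CrtY"),
    e("beta-carotene", "zeaxanthin", "CrtZ"),
    e("beta-carotene", "echinenone", "CrtW"),
    e("echinenone", "canthaxanthin", "CrtW"),
    e("zeaxanthin", "caloxanthin", "CrtG"),
    e("caloxanthin", "nostoxanthin", "CrtG"),
    e("zeaxanthin", "adonixanthin", "CrtW"),
    e("adonixanthin", "astaxanthin", "CrtW"),
    e("zeaxanthin", "erythroxanthin", c("CrtW", "CrtG")),
    e("beta-carotene", "2,2'-dihydroxycanthaxanthin", c("CrtW", "CrtG")),
    e("astaxanthin", "astaxanthin dideoxyglycoside", "CrtX"),
    e("DMAPP", "cytokinin", c("MiaA", "LOG")))
  if (!is.null(config)) {
    if (!file.exists(config)) stopf("pathway config not found: %s", config)
    lines <- readLines(config, warn = FALSE)
    lines <- lines[!startsWith(lines, "#")]
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (!all(c("substrate", "product", "enzymes") %in% header))
      stopf("pathway config line 1: header must name substrate, product, enzymes")
    for (i in seq_along(lines)[-1]) {
      if (!nzchar(trimws(lines[i]))) next
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < length(header))
        stopf("pathway config line %d: expected %d fields, got %d",
              i, length(header), length(f))
      row <- stats::setNames(as.list(f), header)
      enz <- trimws(strsplit(row$enzymes, ",", fixed = TRUE)[[1]])
      if (!length(enz) || any(!nzchar(enz)))
        stopf("pathway config line %d: empty enzyme list", i)
      edges <- rbind(edges, e(row$substrate, row$product, enz,
                              isTRUE(as.logical(row$reversible %||% "FALSE"))))
    }
  }
  # an enzyme-free (spontaneous) cycle would make reachability ill-defined
  free <- edges[lengths(edges$enzymes) == 0L, , drop = FALSE]
  if (nrow(free)) stopf("pathway edges must require at least one enzyme")
  class(edges) <- c("PathwayGraph", class(edges))
  edges
}

#' Producible compound set from an enzyme complement
#'
#' Fixed-point closure: a compound is producible iff it is reachable from
#' the precursor pool using only edges whose full required enzyme set is
#' present.  Terminal compounds are producible compounds with no applicable
#' outgoing edge, excluding the standing precursor pool; they approximate
#' the compounds a strain would accumulate.
#'
#' @param enzymes Character vector of enzyme symbols (e.g. `"CrtE"`,
#'   `"CrtW"`, `"LOG"`).  Case-sensitive.
#' @param graph A [load_pathway_graph()] object.
#' @param precursors Starting pool, default `c("IPP", "DMAPP")`.
#' @return A list with `producible` (character vector, precursors included)
#'   and `terminal` (character vector).
#' @examples
#' producible("CrtE")$terminal  # "GGPP"
#' @export
producible <- function(enzymes, graph = load_pathway_graph(),
                       precursors = c("IPP", "DMAPP")) {
  enzymes <- unique(as.character(enzymes))
  applicable <- vapply(graph$enzymes, function(z) all(z %in% enzymes), TRUE)
  sub <- graph[applicable, , drop = FALSE]
  # expand reversible edges
  if (any(sub$reversible)) {
    rev <- sub[sub$reversible, , drop = FALSE]
    tmp <- rev$substrate; rev$substrate <- rev$product; rev$product <- tmp
    sub <- rbind(sub, rev)
  }
  reach <- precursors
  repeat {
    new <- sub$product[sub$substrate %in% reach & !(sub$product %in% reach)]
    if (!length(new)) break
    reach <- c(reach, unique(new))
  }
  # precursors are a standing pool, not accumulation products
  terminal <- setdiff(reach[!reach %in% sub$substrate], precursors)
  list(producible = reach, terminal = terminal)
}
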