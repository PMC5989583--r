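#' Construct a crt genotype
#'
#' @param strain Strain name.
#' @param symbols Character vector of present crt gene symbols; full names
#'   (`"crtE"`) or single letters (`"E"`) are accepted.
#' @param log,duf2141,pgc Accessory flags: presence of a LOG homologue, of
#'   a DUF2141 homologue, and of a photosynthesis gene cluster.
#' @return An object of class `CrtGenotype`.
#' @export
crt_genotype <- function(strain, symbols, log = FALSE, duf2141 = FALSE,
                         pgc = FALSE) {
  symbols <- normalise_symbols(symbols)
  structure(list(strain = strain, symbols = symbols, log = isTRUE(log),
                 duf2141 = isTRUE(duf2141), pgc = isTRUE(pgc)),
            class = "CrtGenotype")
}

normalise_symbols <- function(symbols) {
  if (!length(symbols)) return(character(0))
  symbols <- as.character(symbols)
  short <- match(toupper(symbols), toupper(sub("^crt", "", CRT_SYMBOLS)))
  full <- match(symbols, CRT_SYMBOLS)
  idx <- ifelse(is.na(full), short, full)
  if (anyNA(idx))
    stopf("unrecognised crt symbol(s): %s",
          paste(symbols[is.na(idx)], collapse = ", "))
  sort(unique(CRT_SYMBOLS[idx]))
}

#' Assign a strain to genotype group I-IV
#'
#' The grouping is a pure function of the crt genotype.  With core =
#' \{crtE, crtB, crtI, crtY, crtZ\}: an incomplete core gives group IV
#' (non-pigmented); core + crtG without crtW gives group I (yellow,
#' nostoxanthin); core + crtG + crtW gives group II (orange); core + crtW
#' without crtG gives group III (red, astaxanthin).  crtX never changes the
#' group.  A complete core with neither crtG nor crtW is left unassigned
#' with the `zeaxanthin_only` caveat (zeaxanthin-producing cells can be
#' yellow, orange or yellow-orange).
#'
#' @param genotype A [crt_genotype()] object (or a character vector of
#'   symbols, which is wrapped).
#' @return An object of class `GroupAssignment` with elements `group` (one
#'   of `"I"`, `"II"`, `"III"`, `"IV"`, `"unassigned"`), `predicted_colour`,
#'   `predicted_carotenoids` and `caveats`.
#' @examples
#' assign_group(c("E", "B", "I", "Y", "Z", "G"))$group  # "I"
#' @export
assign_group <- function(genotype) {
  if (!inherits(genotype, "CrtGenotype"))
    genotype <- crt_genotype("unnamed", genotype)
  syms <- genotype$symbols
  core <- c("crtE", "crtB", "crtI", "crtY", "crtZ")
  has <- function(s) s %in% syms
  if (!all(core %in% syms)) {
    group <- "IV"
  } else if (has("crtG") && has("crtW")) {
    group <- "II"
  } else if (has("crtG")) {
    group <- "I"
  } else if (has("crtW")) {
    group <- "III"
  } else {
    group <- "unassigned"
  }
  colour <- switch(group, I = "yellow", II = "orange", III = "red",
                   IV = "colourless", unassigned = "yellow-orange")
  carotenoids <- switch(group,
    I = c("nostoxanthin", "caloxanthin"),
    II = c("adonixanthin", "astaxanthin", "canthaxanthin", "erythroxanthin",
           "nostoxanthin"),
    III = c("astaxanthin"),
    IV = character(0),
    unassigned = "zeaxanthin")
  if (group == "III" && has("crtX"))
    carotenoids <- c(carotenoids, "astaxanthin dideoxyglycoside")
  caveats <- character(0)
  if (group == "unassigned") caveats <- c(caveats, "zeaxanthin_only")
  # coloured genotypes are occasionally reported colourless (dysfunctional
  # or repressed crtB/crtI)
  if (group != "IV") caveats <- c(caveats, "possible_cryptic_colourless")
  if (genotype$pgc) caveats <- c(caveats, "pgc_present")
  structure(list(strain = genotype$strain, group = group,
                 predicted_colour = colour,
                 predicted_carotenoids = carotenoids, caveats = caveats),
            class = "GroupAssignment")
}

#' Enzyme complement implied by a genotype
#'
#' Maps crt symbols to enzyme names for [producible()].  When the `log`
#' accessory flag is set, MiaA and LOG are both supplied (a miaA homologue
#' is near-ubiquitous in these genomes, so LOG presence is treated as the
#' limiting factor for the cytokinin branch).
#'
#' @param genotype A [crt_genotype()] object.
#' @return Character vector of enzyme symbols.
#' @export
genotype_enzymes <- function(genotype) {
  stopifnot(inherits(genotype, "CrtGenotype"))
  enz <- sub("^crt", "Crt", genotype$symbols)
  if (genotype$log) enz <- c(enz, "MiaA", "LOG")
  enz
}

#' Predict colour and carotenoids, cross-checked against the pathway
#'
#' Combines a [assign_group()] assignment with the [producible()] output
#' for the same genotype.  The group's hallmark carotenoids must be
#' producible (an inconsistency raises an error); for group IV the
#' prediction is the colourless terminal set actually reachable (e.g. GGPP
#' or phytoene).
#'
#' @param assignment A `GroupAssignment`.
#' @param reach Output of [producible()] for the genotype's enzymes.
#' @return The assignment with `predicted_carotenoids` reconciled and a
#'   `producible_terminals` element attached.
#' @export
predict_phenotype <- function(assignment, reach) {
  stopifnot(inherits(assignment, "GroupAssignment"))
  if (assignment$group == "IV") {
    assignment$predicted_carotenoids <- character(0)
  } else {
    missing <- setdiff(assignment$predicted_carotenoids, reach$producible)
    if (length(missing))
      stopf("internal consistency error: group %s prediction not producible: %s",
            assignment$group, paste(missing, collapse = ", "))
  }
  assignment$producible_terminals <- reach$terminal
  assignment
}
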