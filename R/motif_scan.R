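#' Compile a diagnostic protein motif
#'
#' Patterns use the compact notation common in the carotenogenesis
#' literature: fixed residue letters, `x` for any residue, and `(x)n` (also
#' accepted as `(x)_n` or `x(n)`-free text variants with underscores) for a
#' run of exactly `n` wildcards.  `"GxGxxG(x)17E"` therefore compiles to a
#' fixed length of 6 + 17 + 1 = 24.
#'
#' @param pattern Pattern text.
#' @param name Motif name; defaults to the pattern text.
#' @param region Region constraint: `"anywhere"`, `"N-terminal"` or
#'   `"C-terminal"`.
#' @param within For terminal constraints, the window size in residues
#'   (default 60).
#' @return An object of class `Motif` with elements `name`, `pattern`,
#'   `residues` (character vector, `NA` for wildcard positions), `length`,
#'   `region`, `within`.
#' @examples
#' compile_motif("HxxHH")$length  # 5
#' @export
compile_motif <- function(pattern, name = pattern,
                          region = c("anywhere", "N-terminal", "C-terminal"),
                          within = 60L) {
  region <- match.arg(region)
  txt <- gsub("_", "", pattern)
  residues <- character(0)
  i <- 1L
  n <- nchar(txt)
  while (i <= n) {
    ch <- substr(txt, i, i)
    if (ch == "(") {
      close <- regexpr(")", substr(txt, i, n), fixed = TRUE)
      if (close < 0) stopf("malformed pattern '%s': unclosed '(' at position %d",
                           pattern, i)
      inner <- substr(txt, i + 1L, i + close - 2L)
      if (inner != "x")
        stopf("malformed pattern '%s': only '(x)n' groups are supported (position %d)",
              pattern, i)
      i <- i + close
      digits <- regmatches(substr(txt, i, n),
                           regexpr("^[0-9]+", substr(txt, i, n)))
      if (!length(digits))
        stopf("malformed pattern '%s': '(x)' needs a repeat count at position %d",
              pattern, i)
      count <- as.integer(digits)
      if (count < 1L)
        stopf("malformed pattern '%s': repeat count must be >= 1", pattern)
      residues <- c(residues, rep(NA_character_, count))
      i <- i + nchar(digits)
    } else if (ch == "x") {
      residues <- c(residues, NA_character_)
      i <- i + 1L
    } else if (grepl("[A-Z]", ch)) {
      residues <- c(residues, ch)
      i <- i + 1L
    } else {
      stopf("malformed pattern '%s': unexpected character '%s' at position %d",
            pattern, ch, i)
    }
  }
  if (!length(residues)) stopf("malformed pattern '%s': empty", pattern)
  structure(list(name = name, pattern = pattern, residues = residues,
                 length = length(residues), region = region,
                 within = as.integer(within)),
            class = "Motif")
}

#' Scan a protein for a motif
#'
#' Returns all (possibly overlapping) matches, left to right, that satisfy
#' the motif's region constraint.  An N-terminal constraint requires the
#' match to start within the first `within` residues; a C-terminal
#' constraint requires it to end within the last `within`.
#'
#' @param protein Non-empty amino-acid string.
#' @param motif A [compile_motif()] object.
#' @return A data frame with columns `motif`, `start` (0-based offset) and
#'   `match`; zero rows when there is no match.
#' @export
scan_motif <- function(protein, motif) {
  stopifnot(inherits(motif, "Motif"))
  if (!nzchar(protein)) stopf("empty protein sequence")
  L <- nchar(protein)
  k <- motif$length
  if (L < k)
    return(data.frame(motif = character(0), start = integer(0),
                      match = character(0)))
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  fixed <- which(!is.na(motif$residues))
  starts <- integer(0)
  for (s in 0:(L - k)) {
    if (all(chars[s + fixed] == motif$residues[fixed])) starts <- c(starts, s)
  }
  if (motif$region == "N-terminal") starts <- starts[starts < motif$within]
  if (motif$region == "C-terminal") starts <- starts[starts + k > L - motif$within]
  if (!length(starts))
    return(data.frame(motif = character(0), start = integer(0),
                      match = character(0)))
  data.frame(motif = rep(motif$name, length(starts)), start = starts,
             match = substring(protein, starts + 1L, starts + k))
}

#' Default motif panel for crt gene families
#'
#' The diagnostic motifs reported for each family: FAD-binding dinucleotide
#' motifs in CrtY and CrtI, His-rich motifs in CrtZ and CrtW, the conserved
#' prenyltransferase motifs of CrtE, and the PGGxGTxxE motif of LOG.
#'
#' @return A named list mapping gene symbols to lists of `Motif` objects.
#' @export
default_motif_panel <- function() {
  list(
    crtY = list(compile_motif("GxGxxG(x)19E", "FAD_binding_Y", "N-terminal")),
    crtI = list(compile_motif("GxGxxG(x)17E", "FAD_binding_I", "N-terminal")),
    crtZ = list(compile_motif("HxxHH", "His_N", "N-terminal"),
                compile_motif("HxLHH", "His_C", "C-terminal")),
    crtW = list(compile_motif("HDxxH", "His_1"),
                compile_motif("HxxHH", "His_23")),
    crtE = list(compile_motif("GKxxR", "FARM_1"),
                compile_motif("DDxxxxD", "FARM_2"),
                compile_motif("GQxxD", "SARM_1"),
                compile_motif("KT", "SARM_2"),
                compile_motif("DDxxx", "SARM_3")),
    log = list(compile_motif("PGGxGTxxE", "LOG_core"))
  )
}

#' Per-gene motif presence report
#'
#' One row per accepted crt hit, one logical column per motif assigned to
#' that family, plus a `motif_complete` column.  CrtW is motif-complete only
#' when the HDxxH motif is present and the HxxHH motif occurs at least
#' twice (the family carries three His-rich motifs: HDxxH, HxxHH, HxxHH);
#' other families require all their assigned motifs once.
#'
#' @param hits Result of [call_orthologues()].
#' @param genome The `GenomeRecord` supplying protein sequences.
#' @param panel Motif panel, defaults to [default_motif_panel()].
#' @return A data frame with columns `symbol`, `locus_tag`, `motifs_found`,
#'   `motifs_expected`, `motif_complete`.
#' @export
motif_report <- function(hits, genome, panel = default_motif_panel()) {
  rows <- list()
  for (sym in names(hits)) {
    h <- hits[[sym]]
    if (is.null(h) || !sym %in% names(panel)) next
    prot <- genome$features$protein[genome$features$locus_tag == h$subject]
    if (!length(prot) || !nzchar(prot)) next
    found <- character(0)
    counts <- integer(0)
    for (m in panel[[sym]]) {
      nmatch <- nrow(scan_motif(prot, m))
      counts[m$name] <- nmatch
      if (nmatch > 0L) found <- c(found, m$name)
    }
    n_of <- function(nm) if (nm %in% names(counts)) counts[[nm]] else 0L
    complete <- if (sym == "crtW") {
      n_of("His_1") >= 1L && n_of("His_23") >= 2L
    } else {
      length(found) == length(panel[[sym]])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      symbol = sym, locus_tag = h$subject,
      motifs_found = paste(found, collapse = ","),
      motifs_expected = paste(vapply(panel[[sym]], `[[`, "", "name"),
                              collapse = ","),
      motif_complete = complete)
  }
  do.call(rbind, rows) %||%
    data.frame(symbol = character(0), locus_tag = character(0),
               motifs_found = character(0), motifs_expected = character(0),
               motif_complete = logical(0))
}
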