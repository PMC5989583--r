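# Synthetic reference query panel.
#
# The panel proteins are randomly generated at family-typical lengths with
# the family's diagnostic motifs embedded at family-typical positions, so
# that the whole pipeline is exercisable without any real sequence data.
# The panel is deterministic: the same proteins are produced in every
# session.

PANEL_SEED <- 31461L

# family-typical protein lengths (aa)
PANEL_LENGTHS <- c(crtE = 300L, crtB = 310L, crtI = 490L, crtY = 380L,
                   crtZ = 160L, crtG = 240L, crtW = 242L, crtX = 407L,
                   log = 193L, duf2141 = 150L)

# roughly uniprot-like background residue frequencies
AA_FREQ <- c(A = 8.3, R = 5.6, N = 4.0, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
             G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
             P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)

random_protein <- function(len) {
  paste(sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

# overwrite the fixed positions of `pattern` into `chars` starting at
# `offset` (0-based); returns the modified character vector
embed_motif <- function(chars, pattern, offset) {
  m <- compile_motif(pattern)
  fixed <- which(!is.na(m$residues))
  chars[offset + fixed] <- m$residues[fixed]
  chars
}

# (pattern, 0-based offset) of the motifs embedded in each panel protein
PANEL_MOTIFS <- list(
  crtE = list(c("GKxxR", 80), c("DDxxxxD", 95), c("GQxxD", 150),
              c("KT", 180), c("DDxxx", 230)),
  crtI = list(c("GxGxxG(x)17E", 8)),
  crtY = list(c("GxGxxG(x)19E", 6)),
  crtZ = list(c("HxxHH", 30), c("HxLHH", 130)),
  crtW = list(c("HDxxH", 60), c("HxxHH", 110), c("HxxHH", 170)),
  log = list(c("PGGxGTxxE", 70)))

#' Synthetic crt reference query panel
#'
#' Deterministically generated reference proteins for the eight crt gene
#' families plus the LOG and DUF2141 accessory families, at family-typical
#' lengths (e.g. ~300 aa for CrtE) and carrying each family's diagnostic
#' motifs at plausible positions.  Useful as a self-contained stand-in for
#' a user-supplied query panel; being synthetic, it shares no ancestry with
#' any real sequence.
#'
#' @param symbols Which families to include; defaults to all ten.
#' @return Named character vector of protein sequences.
#' @export
crt_reference_panel <- function(symbols = names(PANEL_LENGTHS)) {
  bad <- setdiff(symbols, names(PANEL_LENGTHS))
  if (length(bad)) stopf("unknown panel symbol(s): %s", paste(bad, collapse = ", "))
  with_seed(PANEL_SEED, {
    panel <- vapply(names(PANEL_LENGTHS), function(sym) {
      chars <- strsplit(random_protein(PANEL_LENGTHS[[sym]]), "")[[1]]
      chars[1] <- "M"
      for (m in PANEL_MOTIFS[[sym]] %||% list())
        chars <- embed_motif(chars, m[[1]], as.integer(m[[2]]))
      paste(chars, collapse = "")
    }, "")
    panel[symbols]
  })
}

# 0-based positions that must not be mutated if the family's motifs are to
# survive identity erosion
panel_protected_positions <- function(sym) {
  pos <- integer(0)
  for (m in PANEL_MOTIFS[[sym]] %||% list()) {
    cm <- compile_motif(m[[1]])
    fixed <- which(!is.na(cm$residues))
    pos <- c(pos, as.integer(m[[2]]) + fixed)  # 1-based
  }
  pos
}

#' Write the reference panel as multi-FASTA
#'
#' @param path Output FASTA path.
#' @param symbols Families to include.
#' @return Invisibly, `path`.
#' @export
write_reference_panel <- function(path, symbols = names(PANEL_LENGTHS)) {
  panel <- crt_reference_panel(symbols)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(panel), path)
  invisible(path)
}

#' Read a query panel from multi-FASTA
#'
#' The gene symbol is the first whitespace-delimited token of each header.
#'
#' @param path FASTA path.
#' @return Named character vector of protein sequences.
#' @export
read_query_panel <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}
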