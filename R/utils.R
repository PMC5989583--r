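# internal helpers

# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards.  All stochastic package code funnels through this so
# that identical seeds give byte-identical outputs.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement of an upper-case DNA string (A/C/G/T only).
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Translate a CDS nucleotide string with bacterial genetic code (table 11),
# dropping a trailing stop if present.  Trailing partial codons are ignored.
translate_cds <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, n)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
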