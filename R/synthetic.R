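#' Mutate a protein to a target identity
#'
#' Applies BLOSUM-plausible substitutions (replacement residues drawn from
#' those scoring >= 0 against the original) and, below 85 % target
#' identity, a small deletion and insertion, until the package's own
#' aligner ([align_proteins()]) reports an identity within +/- 0.02 of the
#' target.  Deterministic for a given seed.
#'
#' @param protein Amino-acid string.
#' @param target Target identity fraction in \[0.15, 1\].
#' @param seed Integer seed.
#' @param protect 1-based positions never mutated (e.g. motif residues).
#' @param params Alignment parameters used for the measurement.
#' @return A list with `protein` (mutated) and `identity` (realised, as
#'   measured by the package aligner against the input).
#' @export
mutate_to_identity <- function(protein, target, seed, protect = integer(0),
                               params = alignment_params()) {
  if (!is.numeric(target) || target < 0.15 || target > 1.0)
    stopf("target identity must lie in [0.15, 1.0]")
  if (target == 1.0) return(list(protein = protein, identity = 1.0))
  chars0 <- strsplit(protein, "", fixed = TRUE)[[1]]
  L <- length(chars0)
  sub_mat <- scoring_matrix("BLOSUM62")
  with_seed(seed, {
    mutable <- setdiff(seq_len(L), protect)
    order <- sample(mutable)
    # one replacement residue per position, chosen once
    repl <- vapply(order, function(i) {
      aa <- chars0[i]
      if (!aa %in% AA20) return(sample(AA20, 1))
      ok <- AA20[sub_mat[aa, AA20] >= 0 & AA20 != aa]
      if (!length(ok)) ok <- setdiff(AA20, aa)
      sample(ok, 1)
    }, "")
    # fixed indel plan for low targets, applied for every k
    do_indel <- target <= 0.85 && L > 30
    del_at <- if (do_indel) sample(mutable[mutable < L - 5], 1) else NA
    ins_at <- if (do_indel) sample(mutable[mutable < L - 5], 1) else NA
    ins_res <- if (do_indel) paste(sample(AA20, 2, replace = TRUE),
                                   collapse = "") else ""
    build <- function(k) {
      chars <- chars0
      if (k > 0) chars[order[seq_len(k)]] <- repl[seq_len(k)]
      s <- paste(chars, collapse = "")
      if (do_indel) {
        # delete 2 aa, insert 2 aa (net length preserved)
        s <- paste0(substr(s, 1, del_at - 1), substr(s, del_at + 2, nchar(s)))
        p <- min(ins_at, nchar(s))
        s <- paste0(substr(s, 1, p), ins_res, substr(s, p + 1, nchar(s)))
      }
      s
    }
    measure <- function(s)
      align_proteins(protein, s, params)$identity_fraction
    lo <- 0L; hi <- length(order)
    while (hi > lo) {
      mid <- (lo + hi) %/% 2L
      if (measure(build(mid)) > target) lo <- mid + 1L else hi <- mid
    }
    # probe a small neighbourhood for the k closest to target
    ks <- unique(pmax(0L, pmin(length(order), lo + (-3:3))))
    ids <- vapply(ks, function(k) measure(build(k)), 0)
    best <- which.min(abs(ids - target))
    if (abs(ids[best] - target) > 0.02)
      stopf("could not reach identity %.2f +/- 0.02 (closest realised: %.3f)",
            target, ids[best])
    list(protein = build(ks[best]), identity = ids[best])
  })
}

ARCHITECTURE_TEMPLATES <- c("P1_contiguous", "P2_crtG_separated",
                            "P3_atypical", "P4_YIB_together",
                            "P5_YIG_together", "scattered")

#' Specification for a synthetic genome
#'
#' Defaults emulate the observed properties of the cohort: genomes with a
#' crt locus laid out after one of the six architecture templates, a
#' crtY-crtI reading-frame overlap of 1-8 bp (or a gap of 6-25 bp), G+C
#' content inside the cohort's 0.56-0.68 range, and decoy genes unrelated
#' to carotenogenesis.
#'
#' @param seed Integer seed; the genome is a pure function of the spec.
#' @param template One of `"P1_contiguous"`, `"P2_crtG_separated"`,
#'   `"P3_atypical"`, `"P4_YIB_together"`, `"P5_YIG_together"`,
#'   `"scattered"`.
#' @param genotype crt symbols to plant (letters or full names).
#' @param identity Per-gene target identity vs the reference panel, in
#'   \[0.15, 1\]; a scalar or a named vector by symbol.
#' @param yi Planted crtY-crtI relation:
#'   `list(type = "overlap", bp = 1..8)` or `list(type = "gap", bp = 6..25)`.
#' @param intervening_decoys Decoy ORFs separating crtG from the crtY-I-B
#'   run in the P2 template (1-3).
#' @param log_between Plant a LOG ORF between crtI and crtB.
#' @param duf2141_adjacent Plant a DUF2141 ORF next to crtG.
#' @param genome_length Minimum replicon length in bp.
#' @param gc G+C fraction of background and codon choice, in \[0.50, 0.70\].
#' @param n_decoys Number of decoy ORFs outside the crt blocks.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(seed = 1L, template = "P1_contiguous",
                           genotype = c("E", "B", "I", "Y", "Z", "G"),
                           identity = 0.70,
                           yi = list(type = "overlap", bp = 4L),
                           intervening_decoys = 2L,
                           log_between = FALSE, duf2141_adjacent = FALSE,
                           genome_length = 50000L, gc = 0.62,
                           n_decoys = 15L) {
  template <- match.arg(template, ARCHITECTURE_TEMPLATES)
  genotype <- normalise_symbols(genotype)
  need <- switch(template,
    P1_contiguous = c("crtB", "crtI", "crtY", "crtG"),
    P2_crtG_separated = c("crtB", "crtI", "crtY", "crtG"),
    P3_atypical = c("crtB", "crtI", "crtY"),
    P4_YIB_together = c("crtB", "crtI", "crtY"),
    P5_YIG_together = c("crtB", "crtI", "crtY", "crtG"),
    scattered = character(0))
  miss <- setdiff(need, genotype)
  if (length(miss))
    stopf("template %s requires genotype symbol(s): %s", template,
          paste(miss, collapse = ", "))
  if (!yi$type %in% c("overlap", "gap")) stopf("yi$type must be overlap or gap")
  if (yi$type == "overlap" && !(yi$bp >= 1 && yi$bp <= 8))
    stopf("crtY-crtI overlap must be 1-8 bp")
  if (yi$type == "gap" && !(yi$bp >= 6 && yi$bp <= 25))
    stopf("crtY-crtI gap must be 6-25 bp")
  if (intervening_decoys < 1 || intervening_decoys > 3)
    stopf("intervening_decoys must be 1-3")
  if (gc < 0.50 || gc > 0.70) stopf("gc must lie in [0.50, 0.70]")
  idv <- rep(0.70, length(genotype))
  names(idv) <- genotype
  if (length(identity) == 1L && is.null(names(identity))) {
    idv[] <- identity
  } else {
    nm <- normalise_symbols(names(identity))
    idv[nm] <- unname(identity)
  }
  if (any(idv < 0.15 | idv > 1)) stopf("identity targets must lie in [0.15, 1]")
  if (log_between && !all(c("crtI", "crtB") %in% genotype))
    stopf("log_between needs crtI and crtB in the genotype")
  if (duf2141_adjacent && !"crtG" %in% genotype)
    stopf("duf2141_adjacent needs crtG in the genotype")
  structure(list(seed = as.integer(seed), template = template,
                 genotype = genotype, identity = idv, yi = yi,
                 intervening_decoys = as.integer(intervening_decoys),
                 log_between = isTRUE(log_between),
                 duf2141_adjacent = isTRUE(duf2141_adjacent),
                 genome_length = as.integer(genome_length), gc = gc,
                 n_decoys = as.integer(n_decoys)),
            class = "SyntheticSpec")
}

# codon table 11 back-translation with GC-biased synonymous codon choice
backtranslate <- function(protein, gc) {
  code <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(code), unname(code))
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(chars, function(aa) {
    cands <- by_aa[[aa]]
    if (is.null(cands)) stopf("cannot back-translate residue '%s'", aa)
    gcc <- vapply(strsplit(cands, ""), function(x) sum(x %in% c("G", "C")), 0)
    w <- exp(2 * gc * gcc)  # soft bias towards the target G+C
    sample(cands, 1, prob = w / sum(w))
  }, "")
  codons[1] <- "ATG"
  paste(c(codons, "TAA"), collapse = "")
}

#' Generate a synthetic annotated genome with a ground-truth manifest
#'
#' Plants the genes of `spec$genotype` on a single synthetic replicon after
#' the chosen architecture template, each derived from the synthetic
#' reference panel by [mutate_to_identity()] (diagnostic motif positions
#' are protected from mutation).  The crtY-crtI adjacency equals the spec
#' exactly; reverse-strand genes are reverse-complemented into the genome
#' sequence; decoy ORFs are unrelated random proteins.  The same seed gives
#' byte-identical output.
#'
#' In reading-frame overlaps the downstream CDS sequence takes precedence
#' in the shared bases and the upstream protein is carried by its
#' annotation, as in curated records of translationally coupled genes.
#'
#' @param spec A [synthetic_spec()] object.
#' @param dir Optional output directory; when given, writes
#'   `genome.gbk`, `genome.gff3` + `genome.fna`, and `manifest.tsv`.
#' @return A list with `record` (the `GenomeRecord`), `manifest` (a
#'   `TruthManifest`: per-gene truth plus expected labels) and, when `dir`
#'   is given, `paths`.
#' @export
build_synthetic_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  panel <- crt_reference_panel()
  g <- spec$genotype
  has <- function(s) s %in% g
  with_seed(spec$seed, {
    # --- mutated gene proteins (seeds derived from the master seed) -------
    proteins <- list(); realized <- numeric(0)
    all_syms <- c(g, if (spec$log_between) "log",
                  if (spec$duf2141_adjacent) "duf2141")
    for (i in seq_along(all_syms)) {
      sym <- all_syms[i]
      tgt <- if (sym %in% names(spec$identity)) spec$identity[[sym]] else 0.70
      mut <- mutate_to_identity(panel[[sym]], tgt,
                                seed = (spec$seed * 131L + i) %% 2147483647L,
                                protect = c(1L, panel_protected_positions(sym)))
      proteins[[sym]] <- mut$protein
      realized[sym] <- mut$identity
    }
    # --- layout blocks ----------------------------------------------------
    gene <- function(sym, strand = "+", rel = NULL)
      list(kind = "gene", symbol = sym, strand = strand, rel = rel)
    decoy <- function() list(kind = "decoy", strand = sample(c("+", "-"), 1))
    yi_rel <- spec$yi
    blocks <- list()
    main <- switch(spec$template,
      P1_contiguous = c(list(gene("crtY"), gene("crtI", rel = yi_rel)),
                        if (spec$log_between) list(gene("log")),
                        list(gene("crtB"), gene("crtG", strand = "-"))),
      P2_crtG_separated = c(list(gene("crtY"), gene("crtI", rel = yi_rel)),
                            if (spec$log_between) list(gene("log")),
                            list(gene("crtB")),
                            replicate(spec$intervening_decoys, decoy(),
                                      simplify = FALSE),
                            list(gene("crtG", strand = "-"))),
      P3_atypical = list(gene("crtY", strand = "-"),
                         gene("crtI", strand = "-", rel = yi_rel)),
      P4_YIB_together = c(list(gene("crtY"), gene("crtI", rel = yi_rel)),
                          if (spec$log_between) list(gene("log")),
                          list(gene("crtB"))),
      P5_YIG_together = list(gene("crtY"), gene("crtI", rel = yi_rel),
                             gene("crtG")),
      scattered = list(gene("crtY")))
    blocks[[length(blocks) + 1L]] <- main
    if (spec$template == "P3_atypical") {
      blocks[[length(blocks) + 1L]] <- list(gene("crtB"))
      if (has("crtG")) {
        gb <- list(gene("crtG", strand = "-"))
        if (spec$duf2141_adjacent) gb <- c(gb, list(gene("duf2141", "-")))
        blocks[[length(blocks) + 1L]] <- gb
      }
    }
    if (spec$template == "P4_YIB_together" && has("crtG")) {
      gb <- list(gene("crtG", strand = "-"))
      if (spec$duf2141_adjacent) gb <- c(gb, list(gene("duf2141", "-")))
      blocks[[length(blocks) + 1L]] <- gb
    }
    if (spec$template %in% c("P1_contiguous", "P2_crtG_separated",
                             "P5_YIG_together") && spec$duf2141_adjacent) {
      # duf2141 rides immediately next to crtG inside the main locus
      gi <- which(vapply(main, function(x) identical(x$symbol, "crtG"), TRUE))
      blocks[[1]] <- append(main, list(gene("duf2141", "-")), after = gi)
    }
    if (spec$template == "P5_YIG_together")
      blocks[[length(blocks) + 1L]] <- list(gene("crtB"))
    if (spec$template == "scattered") {
      for (sym in intersect(c("crtI", "crtB", "crtG"), g))
        blocks[[length(blocks) + 1L]] <-
          list(gene(sym, strand = sample(c("+", "-"), 1)))
    }
    if (has("crtZ")) {
      zb <- list()
      if (has("crtW")) zb <- c(zb, list(gene("crtW")))
      zb <- c(zb, list(gene("crtZ")))
      if (has("crtW") && has("crtX")) {
        # crtX immediately downstream of crtW (reading direction): W, X, Z
        zb <- c(list(gene("crtW")), list(gene("crtX")), list(gene("crtZ")))
      }
      blocks[[length(blocks) + 1L]] <- zb
    } else if (has("crtW")) {
      blocks[[length(blocks) + 1L]] <-
        c(list(gene("crtW")), if (has("crtX")) list(gene("crtX")))
    }
    if (has("crtE"))
      blocks[[length(blocks) + 1L]] <- list(gene("crtE"))
    # --- place features ---------------------------------------------------
    inter_block_decoys <- 5L
    feats <- list()
    prev_end <- 150L + sample(0:100, 1)
    place <- function(entry, prev_end) {
      prot <- if (entry$kind == "gene") proteins[[entry$symbol]]
      else sub("^.", "M", random_protein(sample(120:350, 1)))
      dna <- backtranslate(prot, spec$gc)
      if (!is.null(entry$rel)) {
        start <- if (entry$rel$type == "overlap") prev_end - entry$rel$bp
        else prev_end + entry$rel$bp
      } else {
        start <- prev_end + sample(50:300, 1)
      }
      list(symbol = if (entry$kind == "gene") entry$symbol else "decoy",
           strand = entry$strand, start = start,
           end = start + nchar(dna), protein = prot, dna = dna)
    }
    n_placed_decoys <- 0L
    for (b in seq_along(blocks)) {
      if (b > 1L) {
        for (d in seq_len(inter_block_decoys)) {
          f <- place(decoy(), prev_end)
          feats[[length(feats) + 1L]] <- f
          prev_end <- f$end
          n_placed_decoys <- n_placed_decoys + 1L
        }
      }
      for (entry in blocks[[b]]) {
        f <- place(entry, prev_end)
        feats[[length(feats) + 1L]] <- f
        prev_end <- f$end
        if (entry$kind == "decoy") n_placed_decoys <- n_placed_decoys + 1L
      }
    }
    while (n_placed_decoys < spec$n_decoys) {
      f <- place(decoy(), prev_end)
      feats[[length(feats) + 1L]] <- f
      prev_end <- f$end
      n_placed_decoys <- n_placed_decoys + 1L
    }
    total <- max(prev_end + 200L, spec$genome_length)
    # --- genome sequence --------------------------------------------------
    bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE,
                    prob = c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2,
                             (1 - spec$gc) / 2))
    for (f in feats) {
      dna <- if (f$strand == "-") revcomp(f$dna) else f$dna
      bases[(f$start + 1L):f$end] <- strsplit(dna, "", fixed = TRUE)[[1]]
    }
    sequence <- paste(bases, collapse = "")
    # --- assemble record --------------------------------------------------
    df <- do.call(rbind, lapply(feats, function(f)
      data.frame(symbol = f$symbol, start = f$start, end = f$end,
                 strand = f$strand, protein = f$protein)))
    df <- df[order(df$start), , drop = FALSE]
    df$locus_tag <- sprintf("SYN_%04d", seq_len(nrow(df)))
    rid <- sprintf("syncontig_%05d", spec$seed %% 100000L)
    strain <- sprintf("Synthetica carotena sim%d", spec$seed)
    features <- data.frame(
      locus_tag = df$locus_tag, replicon_id = rid, start = df$start,
      end = df$end, strand = df$strand,
      product = ifelse(df$symbol == "decoy", "hypothetical protein",
                       paste0(df$symbol, " family protein")),
      protein = df$protein)
    record <- genome_record(strain,
                            data.frame(replicon_id = rid, length = total),
                            features,
                            stats::setNames(list(sequence), rid),
                            status = "complete")
    genes <- df[df$symbol != "decoy", c("symbol", "locus_tag", "start",
                                        "end", "strand"), drop = FALSE]
    genes$replicon_id <- rid
    genes$target_identity <-
      ifelse(genes$symbol %in% names(spec$identity),
             spec$identity[genes$symbol], 0.70)
    genes$realized_identity <- realized[genes$symbol]
    rownames(genes) <- NULL
    manifest <- structure(list(
      genes = genes, template = spec$template, genotype = spec$genotype,
      yi = spec$yi, log_between = spec$log_between,
      duf2141_adjacent = spec$duf2141_adjacent,
      expected_group = assign_group(crt_genotype(strain, spec$genotype,
                                                 log = spec$log_between))$group),
      class = "TruthManifest")
    out <- list(record = record, manifest = manifest)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      gbk <- file.path(dir, "genome.gbk")
      write_genome(record, gbk, "genbank")
      write_genome(record, file.path(dir, "genome"), "gff3+fasta")
      mtsv <- file.path(dir, "manifest.tsv")
      utils::write.table(genes, mtsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$paths <- c(genbank = gbk, gff3 = file.path(dir, "genome.gff3"),
                     fasta = file.path(dir, "genome.fna"), manifest = mtsv)
    }
    out
  })
}

COHORT_MD5 <- "d9a979c4661cad21efbde1202a23ac20"

#' Load the packaged 41-strain cohort table
#'
#' A machine-readable transcription of the published survey of 41
#' Sphingomonadales strains: species, strain, genome accession and status,
#' crt genotype, genotype group and reported colour.  The file's checksum
#' is verified on load.
#'
#' @return A data frame of 41 rows with a derived `genus` column (first
#'   whitespace-delimited token of the species name).
#' @export
build_cohort_fixture <- function() {
  path <- system.file("extdata", "sphingomonadales_cohort.tsv",
                      package = "crtscan", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), COHORT_MD5))
    stopf("integrity error: cohort fixture checksum mismatch at %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gc_mol_pct = "character"))
  if (nrow(tab) != 41L)
    stopf("integrity error: cohort fixture must have 41 rows, found %d",
          nrow(tab))
  tab$genus <- sub("\\s.*$", "", tab$species)
  tab
}
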