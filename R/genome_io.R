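#' Construct a genome record
#'
#' The uniform in-memory model for an annotated genome.  All internal
#' coordinates are 0-based half-open; conversion to and from the 1-based
#' inclusive conventions of GenBank and GFF3 happens only at the parse and
#' write boundaries.
#'
#' @param strain Strain name.
#' @param replicons Data frame with columns `replicon_id` and `length`.
#' @param features Data frame with columns `locus_tag`, `replicon_id`,
#'   `start` (0-based inclusive), `end` (exclusive), `strand` (`+`, `-` or
#'   `?`), `product`, `protein`.  Optional logical column `compound` marks
#'   join/compound source locations.
#' @param sequences Optional named character vector of replicon nucleotide
#'   sequences (names are replicon ids).
#' @param status `"complete"` or `"draft"`.
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(strain, replicons, features,
                          sequences = NULL, status = c("complete", "draft")) {
  status <- match.arg(status)
  stopifnot(is.data.frame(replicons), is.data.frame(features))
  if (!all(c("replicon_id", "length") %in% names(replicons)))
    stopf("replicons needs columns replicon_id, length")
  req <- c("locus_tag", "replicon_id", "start", "end", "strand",
           "product", "protein")
  miss <- setdiff(req, names(features))
  if (length(miss)) stopf("features missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(features$compound))
    features$compound <- rep(FALSE, nrow(features))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  replicons$length <- as.integer(replicons$length)
  if (nrow(features)) {
    if (any(features$start < 0 | features$start >= features$end))
      stopf("invalid feature interval: need 0 <= start < end")
    if (anyDuplicated(features$locus_tag))
      stopf("locus_tags must be unique within a genome")
    if (!all(features$replicon_id %in% replicons$replicon_id))
      stopf("feature replicon_id not declared: %s",
            paste(setdiff(features$replicon_id, replicons$replicon_id),
                  collapse = ", "))
    if (!all(features$strand %in% c("+", "-", "?")))
      stopf("strand must be one of +, -, ?")
    len <- replicons$length[match(features$replicon_id, replicons$replicon_id)]
    if (any(features$end > len))
      stopf("feature(s) extend beyond replicon bounds: %s",
            paste(features$locus_tag[features$end > len], collapse = ", "))
    features <- features[order(features$replicon_id, features$start), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  features$nucleotide_length <- features$end - features$start
  if (!is.null(sequences)) {
    sequences <- unlist(sequences)
    bad <- setdiff(names(sequences), replicons$replicon_id)
    if (length(bad)) stopf("sequence for undeclared replicon: %s", bad[1])
  }
  structure(list(strain = strain, status = status, replicons = replicons,
                 features = features, sequences = sequences),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("<GenomeRecord> %s [%s]: %d replicon(s), %d CDS feature(s)\n",
              x$strain, x$status, nrow(x$replicons), nrow(x$features)))
  invisible(x)
}

detect_format <- function(path) {
  head <- readLines(path, n = 5L, warn = FALSE)
  if (any(startsWith(head, "LOCUS"))) return("genbank")
  if (any(startsWith(head, "##gff-version"))) return("gff3+fasta")
  stopf("cannot detect format of '%s' (no LOCUS or ##gff-version header)",
        path)
}

#' Parse an annotated genome
#'
#' Reads a GenBank flat file or a GFF3 + FASTA pair into a
#' [GenomeRecord][genome_record()].  1-based inclusive source coordinates
#' are converted to 0-based half-open.  When a CDS carries no translation
#' and the nucleotide sequence is available, the protein is derived with
#' bacterial translation table 11; compound (join) locations are flagged
#' and their protein is taken from the annotation only.  A CDS with neither
#' translation nor nucleotide sequence is skipped with a warning.
#'
#' @param path Path to a GenBank file or to the GFF3 member of a pair (the
#'   FASTA is looked up next to it as `.fna`, `.fa` or `.fasta`).
#' @param format_hint `"genbank"`, `"gff3+fasta"` or `"auto"`.
#' @return A `GenomeRecord`.
#' @export
parse_genome <- function(path, format_hint = c("auto", "genbank", "gff3+fasta")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stopf("file not found: %s", path)
  fmt <- if (format_hint == "auto") detect_format(path) else format_hint
  switch(fmt,
         genbank = parse_genbank(path),
         `gff3+fasta` = parse_gff3_fasta(path))
}

#' Write an annotated genome
#'
#' Serialises a [GenomeRecord][genome_record()] as a GenBank flat file or as
#' the package's own GFF3 + FASTA dialect.  `parse_genome(write_genome(r))`
#' reproduces every feature field exactly, and write-parse-write is
#' byte-stable for the GFF3 dialect.  Unknown-strand features (the draft
#' genome "?" case) are written unstranded (`.`) in GFF3.
#'
#' @param record A `GenomeRecord`.
#' @param path Output path.  For `gff3+fasta` this is treated as a prefix
#'   (or a `.gff3` path whose prefix is reused) and two files
#'   `<prefix>.gff3` and `<prefix>.fna` are written.
#' @param format `"genbank"` or `"gff3+fasta"`.
#' @return Invisibly, the path(s) written.
#' @export
write_genome <- function(record, path, format = c("genbank", "gff3+fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "GenomeRecord"))
  # re-validate bounds through the constructor
  genome_record(record$strain, record$replicons, record$features,
                record$sequences, record$status)
  switch(format,
         genbank = write_genbank(record, path),
         `gff3+fasta` = write_gff3_fasta(record, path))
}

# ---------------------------------------------------------------- GenBank --

wrap_qualifier <- function(text, width = 58L) {
  out <- character(0)
  while (nchar(text) > width) {
    out <- c(out, substr(text, 1L, width))
    text <- substr(text, width + 1L, nchar(text))
  }
  c(out, text)
}

write_genbank <- function(record, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in seq_len(nrow(record$replicons))) {
    rid <- record$replicons$replicon_id[r]
    rlen <- record$replicons$length[r]
    writeLines(sprintf("LOCUS       %-17s %d bp    DNA     linear   BCT 01-JAN-2000",
                       rid, rlen), con)
    writeLines(sprintf("DEFINITION  %s.", record$strain), con)
    writeLines(sprintf("KEYWORDS    %s.", record$status), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rlen), con)
    writeLines(sprintf("                     /organism=\"%s\"", record$strain),
               con)
    fx <- record$features[record$features$replicon_id == rid, , drop = FALSE]
    for (k in seq_len(nrow(fx))) {
      loc <- sprintf("%d..%d", fx$start[k] + 1L, fx$end[k])
      if (fx$strand[k] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         fx$locus_tag[k]), con)
      if (nzchar(fx$product[k]))
        writeLines(paste0("                     ",
                          wrap_qualifier(sprintf("/product=\"%s\"",
                                                 fx$product[k]))), con)
      if (fx$strand[k] == "?")
        writeLines("                     /note=\"strand_uncertain\"", con)
      if (nzchar(fx$protein[k])) {
        tr <- wrap_qualifier(sprintf("/translation=\"%s\"", fx$protein[k]))
        writeLines(paste0("                     ", tr), con)
      }
    }
    writeLines("ORIGIN", con)
    seq <- record$sequences[[rid]] %||% NA_character_
    if (!is.na(seq)) {
      seq <- tolower(seq)
      pos <- seq(1L, nchar(seq), by = 60L)
      for (p in pos) {
        chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
        blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                            pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
        writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

# Parse a (minimal, single- or multi-LOCUS) GenBank flat file.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- which(startsWith(lines, "LOCUS"))
  if (length(locus_idx) == 0L)
    stopf("format error in '%s': no LOCUS record found", path)
  ends <- c(locus_idx[-1] - 1L, length(lines))
  strain <- NA_character_; status <- "complete"
  reps <- list(); feats <- list(); seqs <- list()
  for (b in seq_along(locus_idx)) {
    block <- lines[locus_idx[b]:ends[b]]
    lf <- strsplit(block[1], "[[:space:]]+")[[1]]
    if (length(lf) < 3L || is.na(suppressWarnings(as.integer(lf[3]))))
      stopf("format error in '%s': unparseable LOCUS line '%s'",
            path, block[1])
    rid <- lf[2]; rlen <- as.integer(lf[3])
    def <- grep("^DEFINITION", block, value = TRUE)
    if (length(def)) strain <- sub("\\.$", "", sub("^DEFINITION\\s+", "", def[1]))
    kw <- grep("^KEYWORDS", block, value = TRUE)
    if (length(kw)) {
      kwv <- sub("\\.$", "", sub("^KEYWORDS\\s+", "", kw[1]))
      if (kwv %in% c("complete", "draft")) status <- kwv
    }
    reps[[b]] <- data.frame(replicon_id = rid, length = rlen)
    # features
    fstart <- grep("^FEATURES", block)
    ostart <- grep("^ORIGIN", block)
    fend <- if (length(ostart)) ostart[1] - 1L else length(block)
    if (length(fstart)) {
      ftab <- block[(fstart[1] + 1L):fend]
      key_lines <- grep("^     \\S", ftab)
      key_lines <- c(key_lines, length(ftab) + 1L)
      for (ki in seq_len(length(key_lines) - 1L)) {
        chunk <- ftab[key_lines[ki]:(key_lines[ki + 1L] - 1L)]
        key <- sub("^\\s+", "", substr(chunk[1], 1L, 20L))
        key <- sub("\\s.*$", "", key)
        if (key != "CDS") next
        body <- paste(sub("^\\s{21}", "", chunk[-1]), collapse = "\n")
        loc <- sub("^\\s*CDS\\s+", "", chunk[1])
        # location may continue onto qualifier-free lines (rare; not emitted
        # by this package's writer) -- handled by taking text up to first "/"
        quals <- strsplit(body, "\n/", fixed = TRUE)[[1]]
        if (length(quals) && !startsWith(quals[1], "/") &&
            !grepl("=", quals[1], fixed = TRUE) && !grepl("\"", quals[1])) {
          loc <- paste0(loc, gsub("\\s", "", quals[1])); quals <- quals[-1]
        } else if (length(quals) && startsWith(quals[1], "/")) {
          quals[1] <- sub("^/", "", quals[1])
        }
        parsed <- parse_gb_location(loc, path)
        getq <- function(name) {
          hit <- grep(paste0("^", name, "="), quals, value = TRUE)
          if (!length(hit)) return("")
          v <- sub(paste0("^", name, "="), "", hit[1])
          v <- gsub("\n", "", v, fixed = TRUE)
          gsub("\"", "", v)
        }
        tag <- getq("locus_tag")
        prod <- getq("product")
        tr <- gsub("[[:space:]]", "", getq("translation"))
        strand <- parsed$strand
        if (any(grepl("strand_uncertain", quals, fixed = TRUE))) strand <- "?"
        feats[[length(feats) + 1L]] <- data.frame(
          locus_tag = tag, replicon_id = rid,
          start = parsed$start, end = parsed$end, strand = strand,
          product = prod, protein = tr, compound = parsed$compound)
      }
    }
    # sequence
    if (length(ostart) && ostart[1] < length(block)) {
      sl <- block[(ostart[1] + 1L):length(block)]
      sl <- sl[!startsWith(sl, "//")]
      s <- toupper(gsub("[^acgtnACGTN]", "", paste(sl, collapse = "")))
      if (nzchar(s)) seqs[[rid]] <- s
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(locus_tag = character(0), replicon_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               product = character(0), protein = character(0),
               compound = logical(0))
  finish_record(strain, do.call(rbind, reps), features,
                if (length(seqs)) unlist(seqs) else NULL, status)
}

parse_gb_location <- function(loc, path) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  compound <- grepl("^join\\(|^order\\(", loc)
  nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) < 2L)
    stopf("format error in '%s': unparseable location '%s'", path, loc)
  list(start = min(nums) - 1L, end = max(nums), strand = strand,
       compound = compound)
}

# Shared post-processing: derive missing proteins from sequence (table 11),
# skip CDS with neither translation nor sequence.
finish_record <- function(strain, replicons, features, sequences, status) {
  if (nrow(features)) {
    for (k in seq_len(nrow(features))) {
      if (nzchar(features$protein[k])) next
      if (features$compound[k]) next  # annotation-only for compound locations
      seq <- sequences[[features$replicon_id[k]]] %||% NA_character_
      if (is.na(seq)) next
      cds <- substr(seq, features$start[k] + 1L, features$end[k])
      if (features$strand[k] == "-") cds <- revcomp(cds)
      features$protein[k] <- translate_cds(cds)
    }
    drop <- !nzchar(features$protein)
    if (any(drop)) {
      warnf("skipping %d CDS with no translation and no sequence: %s",
            sum(drop), paste(utils::head(features$locus_tag[drop], 5),
                             collapse = ", "))
      features <- features[!drop, , drop = FALSE]
    }
  }
  genome_record(strain, replicons, features, sequences, status)
}

# ------------------------------------------------------------------- GFF3 --

percent_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

percent_decode <- function(x) {
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

gff3_paths <- function(path) {
  prefix <- sub("\\.gff3?$", "", path)
  list(gff = paste0(prefix, ".gff3"), fna = paste0(prefix, ".fna"))
}

write_gff3_fasta <- function(record, path) {
  p <- gff3_paths(path)
  if (is.null(record$sequences) ||
      !all(record$replicons$replicon_id %in% names(record$sequences)))
    stopf("gff3+fasta output needs nucleotide sequences for every replicon")
  lines <- c("##gff-version 3",
             sprintf("##species %s", percent_encode(record$strain)),
             sprintf("##genome-status %s", record$status),
             sprintf("##sequence-region %s 1 %d",
                     record$replicons$replicon_id, record$replicons$length))
  fx <- record$features
  if (nrow(fx)) {
    strand <- ifelse(fx$strand == "?", ".", fx$strand)
    attrs <- sprintf("ID=%s;product=%s", fx$locus_tag,
                     percent_encode(fx$product))
    lines <- c(lines, sprintf("%s\tcrtscan\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              fx$replicon_id, fx$start + 1L, fx$end,
                              strand, attrs))
  }
  writeLines(lines, p$gff)
  fa <- character(0)
  for (rid in record$replicons$replicon_id) {
    s <- record$sequences[[rid]]
    fa <- c(fa, paste0(">", rid),
            substring(s, seq(1L, nchar(s), 70L),
                      pmin(seq(70L, nchar(s) + 69L, 70L), nchar(s))))
  }
  writeLines(fa, p$fna)
  invisible(c(p$gff, p$fna))
}

parse_gff3_fasta <- function(path) {
  p <- gff3_paths(path)
  if (!file.exists(p$gff)) stopf("file not found: %s", p$gff)
  head <- readLines(p$gff, warn = FALSE)
  strain <- percent_decode(sub("^##species ", "",
                               grep("^##species ", head, value = TRUE)[1]))
  if (is.na(strain)) strain <- basename(p$gff)
  status <- sub("^##genome-status ", "",
                grep("^##genome-status ", head, value = TRUE)[1])
  if (is.na(status) || !status %in% c("complete", "draft")) status <- "complete"
  regions <- grep("^##sequence-region ", head, value = TRUE)
  reps <- NULL
  if (length(regions)) {
    parts <- strsplit(regions, " +")
    reps <- data.frame(replicon_id = vapply(parts, `[`, "", 2),
                       length = as.integer(vapply(parts, `[`, "", 4)))
  }
  gr <- rtracklayer::import(p$gff, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  fna <- NULL
  for (ext in c(".fna", ".fa", ".fasta")) {
    cand <- paste0(sub("\\.gff3?$", "", p$gff), ext)
    if (file.exists(cand)) {
      fna <- Biostrings::readDNAStringSet(cand)
      break
    }
  }
  seqs <- if (!is.null(fna))
    stats::setNames(as.character(fna), sub("\\s.*$", "", names(fna))) else NULL
  if (is.null(reps)) {
    if (is.null(seqs)) stopf("GFF3 without ##sequence-region needs a FASTA")
    reps <- data.frame(replicon_id = names(seqs), length = nchar(seqs))
  }
  n <- length(gr)
  ids <- as.character(gr$ID)
  features <- data.frame(
    locus_tag = ids,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = chartr("*", "?", as.character(GenomicRanges::strand(gr))),
    product = if (!is.null(gr$product)) {
      pr <- as.character(gr$product); pr[is.na(pr)] <- ""; pr
    } else character(n),
    protein = character(n),
    compound = duplicated(ids) | duplicated(ids, fromLast = TRUE))
  # collapse compound (multi-row) features to their overall span
  if (any(features$compound)) {
    keep <- !duplicated(features$locus_tag)
    for (tag in unique(features$locus_tag[features$compound])) {
      rows <- features$locus_tag == tag
      features$start[rows] <- min(features$start[rows])
      features$end[rows] <- max(features$end[rows])
    }
    features <- features[keep, , drop = FALSE]
  }
  finish_record(strain, reps, features, seqs, status)
}

# ------------------------------------------------- start-codon curation ----

#' Optional start-codon curation pass
#'
#' Annotated starts are trusted by default.  This pass re-assigns CDS starts
#' to an in-frame candidate start codon at or upstream of the annotated one
#' (with no intervening in-frame stop codon), preferring start codons in the
#' order ATG > GTG > TTG > CTG and, among equals, the candidate closest to
#' the annotated start.  It needs the nucleotide sequence and leaves
#' unknown-strand and compound features untouched.
#'
#' @param record A `GenomeRecord` with sequences.
#' @param window Maximum upstream extension in bp (in-frame), default 90.
#' @return The record with adjusted features and re-derived proteins.
#' @export
curate_start_codons <- function(record, window = 90L) {
  stopifnot(inherits(record, "GenomeRecord"))
  if (is.null(record$sequences)) stopf("start-codon curation needs sequences")
  preference <- c("ATG", "GTG", "TTG", "CTG")
  stops <- c("TAA", "TAG", "TGA")
  fx <- record$features
  for (k in seq_len(nrow(fx))) {
    if (fx$strand[k] == "?" || fx$compound[k]) next
    seq <- record$sequences[[fx$replicon_id[k]]] %||% NA_character_
    if (is.na(seq)) next
    # offsets (bp upstream of annotated start, multiples of 3), 0 included
    best_rank <- Inf; best_off <- NA_integer_
    for (off in seq(0L, window, by = 3L)) {
      if (fx$strand[k] == "+") {
        s <- fx$start[k] - off
        if (s < 0L) break
        codon <- substr(seq, s + 1L, s + 3L)
      } else {
        e <- fx$end[k] + off
        if (e > nchar(seq)) break
        codon <- revcomp(substr(seq, e - 2L, e))
      }
      if (off > 0L && codon %in% stops) break
      rank <- match(codon, preference)
      if (!is.na(rank) && rank < best_rank) {
        best_rank <- rank; best_off <- off
        if (rank == 1L) break
      }
    }
    if (!is.na(best_off) && best_off > 0L) {
      if (fx$strand[k] == "+") fx$start[k] <- fx$start[k] - best_off
      else fx$end[k] <- fx$end[k] + best_off
      cds <- substr(seq, fx$start[k] + 1L, fx$end[k])
      if (fx$strand[k] == "-") cds <- revcomp(cds)
      fx$protein[k] <- translate_cds(cds)
    }
  }
  genome_record(record$strain, record$replicons, fx, record$sequences,
                record$status)
}
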