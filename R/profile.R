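#' Detect a photosynthesis gene cluster (PGC) heuristically
#'
#' Given a second query panel of PGC proteins (e.g. bch / puf / crtC-D-F
#' families), the cluster is called present iff at least `min_hits`
#' accepted panel hits fall within one `window_bp` window on a single
#' replicon.  A labelled heuristic: it mirrors the footnote-style "PGC"
#' annotation, not a curated cluster reconstruction.
#'
#' @param pgc_hits [call_orthologues()] result for the PGC panel.
#' @param genome The `GenomeRecord`.
#' @param min_hits Minimum accepted hits in the window, default 6.
#' @param window_bp Window size, default 50000.
#' @return Logical.
#' @export
pgc_present <- function(pgc_hits, genome, min_hits = 6L, window_bp = 50000L) {
  hf <- hit_features(pgc_hits, genome)
  if (nrow(hf) < min_hits) return(FALSE)
  for (rid in unique(hf$replicon_id)) {
    st <- sort(hf$start[hf$replicon_id == rid])
    n <- length(st)
    if (n < min_hits) next
    for (i in seq_len(n - min_hits + 1L))
      if (st[i + min_hits - 1L] - st[i] <= window_bp) return(TRUE)
  }
  FALSE
}

#' Profile one genome end to end
#'
#' Runs the full pipeline: orthologue calling against the crt panel, locus
#' construction and architecture classification, crtY-crtI co-occurrence,
#' motif report, genotype group assignment and pathway reachability.
#'
#' @param genome A `GenomeRecord` (or a path, which is parsed).
#' @param panel Query panel (named protein vector); defaults to the
#'   packaged synthetic reference panel.
#' @param criteria,params Orthology criteria and alignment parameters.
#' @param graph Pathway graph.
#' @param pgc_panel Optional PGC query panel for the PGC caveat flag.
#' @param motif_panel Motif panel for the motif report.
#' @param include_plasmids Unused placeholder for multi-replicon input
#'   filtering (all replicons of the record are profiled; pre-filter the
#'   record to restrict to chromosome-like replicons).
#' @return A `StrainProfile` list: `strain`, `genotype` (a
#'   [crt_genotype()]), `hits`, `loci`, `architecture`, `yi`, `motifs`,
#'   `assignment`, `producible`.
#' @export
profile_genome <- function(genome, panel = crt_reference_panel(),
                           criteria = orthology_criteria(),
                           params = alignment_params(),
                           graph = load_pathway_graph(),
                           pgc_panel = NULL,
                           motif_panel = default_motif_panel(),
                           include_plasmids = FALSE) {
  if (is.character(genome)) genome <- parse_genome(genome)
  stopifnot(inherits(genome, "GenomeRecord"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s failed for %s: %s", name, genome$strain,
            conditionMessage(e)))
  }
  hits <- stage("homology", call_orthologues(panel, genome, criteria, params))
  crt_syms <- intersect(names(hits)[!vapply(hits, is.null, TRUE)],
                        CRT_SYMBOLS)
  pgc <- if (!is.null(pgc_panel)) {
    stage("pgc", pgc_present(
      call_orthologues(pgc_panel, genome, criteria, params), genome))
  } else FALSE
  genotype <- crt_genotype(genome$strain, crt_syms,
                           log = !is.null(hits$log),
                           duf2141 = !is.null(hits$duf2141),
                           pgc = pgc)
  loci <- stage("loci", build_loci(hits, genome))
  arch <- stage("architecture", classify_architecture(loci, genome, hits))
  yi <- stage("yi", yi_cooccurrence(hits, genome))
  motifs <- stage("motifs", motif_report(hits, genome, motif_panel))
  assignment <- stage("classification", assign_group(genotype))
  reach <- stage("pathway", producible(genotype_enzymes(genotype), graph))
  assignment <- stage("phenotype", predict_phenotype(assignment, reach))
  structure(list(strain = genome$strain, status = genome$status,
                 genotype = genotype, hits = hits, loci = loci,
                 architecture = arch, yi = yi, motifs = motifs,
                 assignment = assignment, producible = reach),
            class = "StrainProfile")
}

#' @export
print.StrainProfile <- function(x, ...) {
  cat(sprintf("<StrainProfile> %s\n  genotype: %s\n  group: %s (%s)\n  pattern: %s\n",
              x$strain, paste(x$genotype$symbols, collapse = ","),
              x$assignment$group, x$assignment$predicted_colour,
              x$architecture$pattern_label))
  invisible(x)
}

cohort_from_fixture <- function(fixture) {
  lapply(seq_len(nrow(fixture)), function(i) {
    list(strain = paste(fixture$species[i], fixture$strain[i]),
         species = fixture$species[i], genus = fixture$genus[i],
         status = fixture$status[i],
         symbols = normalise_symbols(
           strsplit(fixture$genotype[i], ",", fixed = TRUE)[[1]]),
         group = fixture$group[i])
  })
}

#' Cohort-level summary
#'
#' Counts across a set of strain profiles, or across the packaged cohort
#' fixture in genotype-only mode (architecture- and overlap-level fields
#' are then `NA`).
#'
#' @param profiles A list of [profile_genome()] results, or a data frame in
#'   the cohort-fixture layout (see [build_cohort_fixture()]).
#' @return A list of class `CohortSummary`: `n_strains`, `n_complete`,
#'   `symbol_counts`, `n_with_both_YI`, `genus_counts`, `group_counts`,
#'   and (profiles mode) `yi`.
#' @export
cohort_summary <- function(profiles) {
  if (is.data.frame(profiles)) {
    entries <- cohort_from_fixture(profiles)
    groups <- vapply(entries, `[[`, "", "group")
    yi <- NULL
  } else {
    entries <- lapply(profiles, function(p)
      list(strain = p$strain,
           genus = sub("\\s.*$", "", p$strain),
           status = p$status, symbols = p$genotype$symbols,
           group = p$assignment$group))
    groups <- vapply(entries, `[[`, "", "group")
    yi <- yi_summary(do.call(rbind, lapply(profiles, `[[`, "yi")))
  }
  n <- length(entries)
  if (n == 0L) {
    return(structure(list(
      n_strains = 0L, n_complete = 0L,
      symbol_counts = stats::setNames(integer(length(CRT_SYMBOLS)),
                                      CRT_SYMBOLS),
      n_with_both_YI = 0L, genus_counts = integer(0),
      group_counts = c(I = 0L, II = 0L, III = 0L, IV = 0L, unassigned = 0L),
      yi = NULL), class = "CohortSummary"))
  }
  symsets <- lapply(entries, `[[`, "symbols")
  symbol_counts <- vapply(CRT_SYMBOLS, function(s)
    sum(vapply(symsets, function(z) s %in% z, TRUE)), 0L)
  genus <- vapply(entries, `[[`, "", "genus")
  structure(list(
    n_strains = n,
    n_complete = sum(vapply(entries, `[[`, "", "status") == "complete"),
    symbol_counts = symbol_counts,
    n_with_both_YI = sum(vapply(symsets, function(z)
      all(c("crtY", "crtI") %in% z), TRUE)),
    genus_counts = table(genus),
    group_counts = vapply(c("I", "II", "III", "IV", "unassigned"),
                          function(gr) sum(groups == gr), 0L),
    yi = yi), class = "CohortSummary")
}

#' Write a strain profile as TSV tables and a locus diagram
#'
#' Deterministic output: stable sort orders and fixed number formatting, so
#' re-running on identical inputs is byte-identical.
#'
#' @param profile A `StrainProfile`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(hits = file.path(dir, "hits.tsv"),
             loci = file.path(dir, "loci.txt"),
             summary = file.path(dir, "summary.tsv"))
  write_hit_table(profile$hits, paths[["hits"]])
  writeLines(locus_diagram(profile$loci), paths[["loci"]])
  s <- profile
  summary <- data.frame(
    field = c("strain", "genotype", "group", "predicted_colour",
              "predicted_carotenoids", "pattern_label", "caveats",
              "producible_terminals"),
    value = c(s$strain, paste(s$genotype$symbols, collapse = ","),
              s$assignment$group, s$assignment$predicted_colour,
              paste(s$assignment$predicted_carotenoids, collapse = ","),
              s$architecture$pattern_label,
              paste(s$assignment$caveats, collapse = ","),
              paste(sort(s$assignment$producible_terminals), collapse = ",")))
  utils::write.table(summary, paths[["summary"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
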