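---
title: "Profiling carotenogenesis gene clusters with crtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling carotenogenesis gene clusters with crtscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtscan)
```

## The problem

Bacteria of the order *Sphingomonadales* show a striking range of colony
colours — yellow, orange, red, pink, and colourless — that traces back to
which carotenoid biosynthesis (*crt*) genes a strain carries.  Eight gene
families matter here: *crtE* (GGPP synthase), *crtB* (phytoene synthase),
*crtI* (phytoene desaturase), *crtY* (lycopene cyclase), *crtZ*
(β-carotene 3,3′-hydroxylase), *crtG* (carotenoid 2,2′-hydroxylase),
*crtW* (β-carotene 4,4′-ketolase) and *crtX* (carotenoid
glycosyltransferase), plus two accessory families that travel with *crt*
loci: LOG (cytokinin phosphoribohydrolase) and DUF2141.

`crtscan` turns an annotated genome into a strain profile: which *crt*
orthologues it carries, how they are organised on the chromosome, whether
the diagnostic protein motifs are intact, which genotype group (I–IV) the
strain falls into, and which carotenoids the enzyme complement can reach.

## Orthologue calling

Candidate orthologues are found by optimal Smith–Waterman local alignment
with affine gaps (BLOSUM62, gap open 11, gap extend 1; a gap of length $k$
costs $11 + k$).  Raw scores $S$ are converted with the Karlin–Altschul
relations

$$\mathrm{bit} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m \, n \, 2^{-\mathrm{bit}},$$

with the published gapped BLOSUM62/11,1 constants $\lambda = 0.267$,
$K = 0.041$ as defaults.  A candidate is accepted iff all four criteria
hold: identity $\ge$ 30 % (inclusive), length difference $<$ 20 %
(strict), bit score $\ge$ 50 (inclusive) and E-value $< 10^{-10}$
(strict).  When several candidates pass for one query, the highest percent
identity wins; ties fall back to bit score, then to the lexicographically
smallest locus tag, so results are deterministic.

Three denominators are underdetermined by the verbal criteria and are
fixed as package conventions:

* identity = identical columns / total alignment columns, gap columns
  included (the BLAST convention);
* length difference = |query length − subject length| / query length;
* the E-value search space $n$ is the summed proteome length of the
  genome, mirroring a one-proteome database search.

Exact numerical agreement with any particular search engine's E-values is
not a goal: the criteria are thresholds, and both the synthetic data and
the tests operate well clear of them.  Synteny (conserved order and
orientation) is reported as locus-architecture output, never used as a
filter that deletes hits, because the verbal criterion is not quantified.

The traceback is deterministic (ties broken diagonal, then up, then left),
`X` is accepted and scored 0 against everything, and the aligner is tested
for exact score agreement against an independent brute-force enumeration
of all local alignments on short peptides.

## Coordinates and genome I/O

All internal coordinates are 0-based half-open; GenBank's and GFF3's
1-based inclusive coordinates are converted only at the parse/write
boundary.  This makes overlap arithmetic unambiguous:
`overlap = max(0, min(end_u, end_d) − max(start_u, start_d))`.

Annotated start codons are trusted as-is.  An optional curation pass
(`curate_start_codons()`) re-assigns starts to the preferred in-frame
candidate at or upstream of the annotation (ATG > GTG > TTG > CTG, nearest
first among equals, never crossing an in-frame stop), as a reproducible
stand-in for manual start-codon curation.  It is off by default because it
alters annotations.

CDS with a `/translation` keep it verbatim; otherwise the protein is
derived from the nucleotide sequence with bacterial translation table 11.
Compound (`join`) locations are flagged and their protein is taken from
the annotation only.  Features on different contigs of a draft genome are
never asserted adjacent — co-location simply fails across contigs.

## Locus architecture

A locus is a maximal run of accepted *crt* hits in which consecutive
members are separated by at most 3 annotated CDS and at most 10 kb.  Both
knobs are configurable; the field describes co-location verbally
("adjacent", "separated by 1–3 ORFs") without a bp bound, so 10 kb was
chosen once as a generous same-neighbourhood bound and left alone.

The observed architectures are labelled:

| label | meaning |
|---|---|
| `P1_contiguous` | one locus holds *crtB/I/Y/G* with no separating ORFs |
| `P2_crtG_separated` | *crtY/I/B* contiguous; *crtG* in the locus but set apart by 1–3 ORFs |
| `P4_YIB_together` | *crtY/I/B* co-located; *crtG* elsewhere |
| `P5_YIG_together` | *crtY/I/G* co-located; *crtB* elsewhere |
| `P3_atypical` | *crtY/I* translocated away from *crtB*, strands mixed |
| `scattered` / `partial` | no pattern / fewer than two of *crtY/I/B* |

Accepted LOG and DUF2141 hits are *not* counted as separating ORFs: these
accessory genes sit inside many *crt* loci (LOG typically between *crtI*
and *crtB*), and counting them as separators would misclassify a
contiguous locus.  The flag `log_between_crtI_crtB` is true iff exactly
one CDS lies between *crtI* and *crtB* and it is an accepted LOG hit.

"Immediately upstream of *crtZ*" is interpreted relative to *crtZ*'s
reading direction (strand-aware), not raw coordinates; likewise
`crtX_downstream_of_crtW` relative to *crtW*.  The co-occurrence record
for *crtY*–*crtI* reports presence, co-location, co-orientation and the
reading-frame overlap (1–8 bp in practice, modally 4 bp) or separation
(6–25 bp) — the hallmark of translational coupling, where the downstream
ribosome-binding site lies inside the upstream ORF.

## Pathway reachability

The pathway graph has 16 default edges: the backbone
IPP ⇌ DMAPP → GGPP → phytoene → lycopene → β-carotene → zeaxanthin, the
zeaxanthin branches to nostoxanthin (CrtG via caloxanthin), astaxanthin
(CrtW via adonixanthin) and erythroxanthin (CrtW+CrtG), the β-carotene
branches to canthaxanthin (CrtW via echinenone) and
2,2′-dihydroxycanthaxanthin (CrtW+CrtG), glycosylation of astaxanthin by
CrtX, and the cytokinin branch from DMAPP (MiaA+LOG).  A compound is
producible iff reachable from the precursor pool {IPP, DMAPP} using only
edges whose full enzyme set is present; terminals (producible compounds
with no applicable outgoing edge, the precursor pool excluded) approximate
what a strain accumulates.  Accumulation of transient intermediates is not
modelled.

Two modelling choices were genuinely open and are resolved as follows.
The astaxanthin route from zeaxanthin is modelled through adonixanthin
under CrtW alone, which makes astaxanthin reachable for the
*crtW*-carrying groups without requiring CrtG.  Whether CrtG acts on
astaxanthin (2-hydroxyastaxanthin is reported for *Brevundimonas*) is left
out of the defaults; the TSV edge-list override can add it, as it can add
the spirilloxanthin branch (CrtC/CrtD/CrtF) relevant to strains with
photosynthesis gene clusters.

## Genotype groups

With core = {*crtE, crtB, crtI, crtY, crtZ*}:

* incomplete core → **group IV**, colourless (terminals are then GGPP or
  phytoene — colourless compounds — or nothing);
* core + *crtG*, no *crtW* → **group I**, yellow, nostoxanthin
  (+ caloxanthin);
* core + *crtG* + *crtW* → **group II**, orange, adonixanthin /
  astaxanthin / canthaxanthin / erythroxanthin (+ the nostoxanthin
  branch);
* core + *crtW*, no *crtG* → **group III**, red, astaxanthin (and its
  dideoxyglycoside when *crtX* is present);
* complete core with neither → **unassigned**, with the `zeaxanthin_only`
  caveat, predicted yellow–orange (zeaxanthin producers span that range).

*crtX* never changes the group — it only extends the predicted compounds.
A hypothetical core+G+W+X genotype is therefore group II.  Every non-IV
assignment carries the `possible_cryptic_colourless` caveat: strains with
a complete coloured genotype are occasionally reported colourless
(dysfunctional or repressed *crtB*/*crtI*), so colour predictions are
upper bounds.  A detected photosynthesis gene cluster adds `pgc_present`
(spirilloxanthin and Bchl *a* production can shift the observed colour)
but never changes the group.  PGC detection itself is a labelled
heuristic: at least 6 accepted hits from a user-supplied PGC panel inside
one 50 kb window.

One documented mismatch between the verbal grouping and the pathway
model: over all $2^8$ hypothetical genotypes, a group IV strain (core
incomplete) can still reach coloured compounds — {E,B,I,Y} reaches
β-carotene, {E,B,I,Y,W} reaches canthaxanthin.  No such genotype occurs in
the cohort, whose four group IV strains ({E,I,Y}, {E,I}, {E,Y}, {E}) all
stall before phytoene; the consistency test therefore checks the cohort's
group IV genotypes, plus hallmark-compound reachability for groups
I/II/III over all $2^8$ genotypes.

## The synthetic generator

`build_synthetic_genome()` emits an annotated replicon plus a ground-truth
manifest, so every pipeline stage is testable without downloads.  Its
defaults are the study conditions, chosen once:

* reference panel: randomly generated proteins at family-typical lengths
  (e.g. ~300 aa CrtE, 193 aa LOG) with each family's diagnostic motifs
  embedded — entirely synthetic, sharing no ancestry with real sequences;
* per-gene identity vs the panel: 0.70 by default, configurable in
  [0.15, 1]; identity erosion is driven by the package's own aligner
  (substitutions drawn from residues scoring ≥ 0 in BLOSUM62, one small
  deletion+insertion below 85 %) until the realised identity is within
  ±0.02 of target; motif positions and the initiator Met are protected;
* *crtY*–*crtI* geometry: overlap 1–8 bp (default 4, the modal value) or
  gap 6–25 bp, planted exactly;
* G+C 0.62 (inside the cohort's 0.56–0.68 range), biasing both background
  sequence and synonymous codon choice;
* intergenic spacers uniform in [50, 300] bp except where an
  overlap/gap is planted; blocks that must not merge into one locus are
  separated by 5 decoy ORFs;
* 15 decoy ORFs (random proteins of 120–350 aa) at default.

In a planted reading-frame overlap the downstream CDS takes precedence in
the shared bases; the upstream protein is carried by its annotation, as in
curated records of translationally coupled genes, so re-deriving the
upstream protein from the GFF3+FASTA pair can differ in its last one or
two residues.  Everything is a pure function of the spec's seed — the same
seed yields byte-identical files.

What the generator does *not* emulate: realistic codon usage, evolution
along a phylogeny, annotation errors (wrong starts, frameshifts,
split/merged ORFs), draft-genome fragmentation of loci across contigs, and
paralogy.  Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under clean annotations at the planted
identity levels, not that it is robust to the full messiness of real
drafts.

## The packaged cohort table

A 41-row machine-readable table (species, strain, accession, genome
status, *crt* genotype, group, reported colour) ships with the package and
is checksum-verified on load.  Its countable facts — 41 strains, 34
complete genomes, 37 *crtZ* carriers of which 8 (~22 %) carry *crtW*, 38
strains with both *crtY* and *crtI*, group sizes 29/7/1/4, 12
*Sphingomonas* — are reproduced by `cohort_summary()` and asserted exactly
in the acceptance tests.  The cohort-wide overlap census (28 strains with
a 1–8 bp overlap) needs the real genome sequences and is not desk-scale;
it is covered instead by the planted-geometry recovery tests across all
six architecture templates and ≥ 20 seeds each.

## Numerical and testing choices

* Alignment-oracle tests enumerate all local alignments by brute force;
  exhaustively for all peptide pairs up to length 2 over a 4-letter
  alphabet and for random samples at lengths 3–5 (the enumeration grows
  too fast beyond that to be exhaustive in-suite).
* Pathway closure is verified against an independent igraph reachability
  computation for all $2^8$ crt enzyme subsets.
* The recovery suite runs 6 templates × 20 seeds (120 genomes) at the
  generator defaults; the acceptance script re-runs 6 × 5 with seeds
  derived from its `--seed`.
* Degenerate inputs: empty proteomes yield empty hit maps (not errors),
  empty hit sets yield empty locus lists, the empty enzyme set yields the
  precursor pool, and unclassifiable architectures are labelled
  `scattered` with a logged note.

## Limitations

The profiler trusts annotations; it performs no gene prediction, so a
genuinely present but unannotated *crt* gene is invisible.  Heuristic
seeding is deliberately absent — alignment is exact and O(mn), sized for
bacterial proteomes, not metagenomes.  Phylogenetics, secondary-structure
analysis and quantitative colour/intensity prediction are out of scope.
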