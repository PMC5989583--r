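# crtscan

Genotype profiling of carotenoid biosynthesis (*crt*) gene clusters in
annotated bacterial genomes, built around the genetics of pigmentation in
the order *Sphingomonadales*.

Colony colour in these bacteria — yellow, orange, red, or colourless — is
largely determined by which of eight *crt* genes a strain carries: *crtE*
(GGPP synthase), *crtB* (phytoene synthase), *crtI* (phytoene desaturase),
*crtY* (lycopene cyclase), *crtZ* (β-carotene 3,3′-hydroxylase), *crtG*
(carotenoid 2,2′-hydroxylase), *crtW* (β-carotene 4,4′-ketolase) and
*crtX* (carotenoid glycosyltransferase).  `crtscan` reimplements the full
comparative-genomics workflow behind that observation as a reusable,
tested pipeline:

* **Orthologue calling** by exact Smith–Waterman local alignment (BLOSUM62,
  affine gaps 11/1) with Karlin–Altschul statistics
  (`bit = (λS − ln K)/ln 2`, `E = mn·2^−bit`) and the composite acceptance
  rule: identity ≥ 30 %, length difference < 20 %, bit ≥ 50, E < 1e−10;
  best hit by highest identity.
* **Locus architecture**: grouping hits into loci, reading-frame
  overlap/gap computation (the *crtY*–*crtI* 1–8 bp coupling overlap, modally
  4 bp), intervening-ORF counts, and classification into the observed
  patterns (contiguous, *crtG*-separated, *crtY/I/B* together, *crtY/I/G*
  together, atypical, scattered), with flags for the accessory LOG and
  DUF2141 genes that ride inside *crt* loci.
* **Motif scanning** in the field's compact notation (`GxGxxG(x)19E`,
  `HxxHH`, `PGGxGTxxE`, ...) with N-/C-terminal region constraints.
* **Genotype → group classification** (groups I–IV plus unassigned) with
  predicted colour and carotenoids.
* **Pathway reachability** over the carotenoid biosynthesis graph
  (zeaxanthin as the branchpoint towards nostoxanthin, astaxanthin and
  erythroxanthin), computing producible and terminal compounds from an
  enzyme complement.
* **A synthetic-genome generator** with ground-truth manifests, plus a
  packaged, checksum-verified 41-strain cohort table, so the whole
  pipeline builds and tests without any downloads.

## Worked example

Simulate a genome whose *crt* locus follows the "*crtG* set apart"
architecture, with a LOG gene between *crtI* and *crtB*, then profile it:

```r
library(crtscan)

spec <- synthetic_spec(seed = 7, template = "P2_crtG_separated",
                       log_between = TRUE)
out <- build_synthetic_genome(spec)
pr  <- profile_genome(out$record)
pr
#> <StrainProfile> Synthetica carotena sim7
#>   genotype: crtB,crtE,crtG,crtI,crtY,crtZ
#>   group: I (yellow)
#>   pattern: P2_crtG_separated

locus_diagram(pr$loci)
#> syncontig_00007: crtY(+) -overlap 4bp- crtI(+) -gap 93bp- log(+) -gap 97bp- crtB(+) -gap 1415bp- crtG(-)
#> syncontig_00007: crtZ(+)
#> syncontig_00007: crtE(+)

pr$yi
#>   both_present co_located co_oriented overlap_bp gap_bp
#> 1         TRUE       TRUE        TRUE          4      0

pr$assignment$producible_terminals
#> [1] "cytokinin"    "nostoxanthin"
```

Reading the output: all six group-I genes were recovered at the planted
identities; *crtY* and *crtI* overlap by exactly the planted 4 bp (the
translational-coupling signature); *crtE* and *crtZ* sit away from the
main locus, as they do in real genomes of this order; and the enzyme
complement reaches nostoxanthin — the hallmark carotenoid of yellow,
group-I strains (cytokinin appears because a LOG homologue was planted).

The packaged cohort table reproduces the survey-level counts:

```r
s <- cohort_summary(build_cohort_fixture())
s$n_strains          # 41
s$symbol_counts      # crtE 41, crtZ 37, crtW 8, ...
s$group_counts       # I 29, II 7, III 1, IV 4
```

A thin command-line wrapper lives in `inst/cli/crtscan.R`
(`scan`, `cohort`, `simulate`, `classify`, `pathway` subcommands).

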