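# mirtas

Homology-based discovery of conserved plant miRNAs and tasiRNA (TAS) loci
in a transcriptome, with classification of small-RNA responses to
simulated insect herbivory.

## The problem

Conserved microRNAs can be found in an unannotated plant transcriptome by
searching known mature sequences against it, because matures of 20–24 nt
are strongly conserved across species. But a sequence match is weak
evidence on its own: a genuine miRNA locus must sit in a non-coding
transcript that folds into a stable stem-loop with the mature on one arm.
Trans-acting siRNA (TAS) loci add a second layer — a miRNA trigger
(miR390 for TAS3, miR828 for TAS4) cleaves the transcript and phased
21-nt small RNAs are produced downstream of the cut. Once candidate
small RNAs exist, the ecological question is how they respond to
herbivory: wounding (W+W), wounding plus larval oral secretions (W+OS),
and whether the response requires jasmonate signaling (tested with a
JA-deficient ir-*aoc* genotype).

`mirtas` implements that whole chain as composable R functions:

1. **Discovery** — exhaustive ungapped scan of catalog matures against
   both strands of every transcript with a Hamming budget (default ≤ 4);
   6-frame longest-ORF coding filter; precursor window extraction.
2. **Folding** — Zuker-style minimum-free-energy dynamic program
   (nearest-neighbor stacking + loop penalties, G:U allowed, min loop 3,
   no pseudoknots), and stem-loop validation: one hairpin in the
   mature's unit, mature on one arm, ≥ 60% of it paired, MFE ≤ −15
   kcal/mol.
3. **Targets & TAS** — complementarity scan (mismatches and G:U wobbles
   scored separately, score = mm + w·wob ≤ 4), cleavage placed between
   the target bases paired to miRNA positions 10/11, phased 21-nt
   windows tiled 3' of the cut.
4. **Phylogeny** — p-distance / Jukes–Cantor, classical neighbor
   joining (exact on additive matrices), column-bootstrap support,
   Newick I/O.
5. **Expression** — Livak 2^−ΔΔCt quantification against a
   housekeeping reference, 75th-percentile + log2 microarray
   normalization, one-way ANOVA with Fisher's *protected* LSD and
   compact letter displays, and the four-way response classification
   (wound-/OS-inducible × JA-dependent/-independent/-suppressed).
6. **Synthetic data** — deterministic generators for transcriptomes
   with planted precursors and coding decoys, TAS transcripts, qPCR
   tables with response archetypes, and microarray matrices — each with
   machine-readable ground truth.

The packaged reference catalog is a 59-entry *Nicotiana attenuata*
mature-miRNA set (36 families; 52 entries with a recorded precursor MFE,
mean −62.1 kcal/mol).

## Worked example

```r
library(mirtas)
cat59 <- read_mirna_catalog()
summarize_catalog(cat59)
#> miRNA catalog summary
#>   entries:  59 in 36 families
#>   with MFE: 52   without: 7
#>   MFE kcal/mol: mean -62.1, range [-104.3, -33.3]

# a small synthetic transcriptome with two planted precursors
sim <- generate_transcriptome(cat59,
  planted = data.frame(name = c("Nat-miR390a", "Nat-miR828"), n_sub = c(0, 2)),
  n_transcripts = 50, n_coding_decoys = 2, length_range = c(300, 800), seed = 7)
queries <- setNames(cat59$sequence[match(c("Nat-miR390a", "Nat-miR828"), cat59$name)],
                    c("Nat-miR390a", "Nat-miR828"))
hits <- scan_homologs(queries, sim$transcripts, max_mismatch = 4)
hits[, 1:6]
#>         query  transcript start end strand mismatches
#> 1 Nat-miR390a NA454_00024   461 482      +          0
#> 2 Nat-miR390a NA454_00024   510 531      -          0
#> 3  Nat-miR828 NA454_00041   646 668      +          2
#> 4  Nat-miR828 NA454_00041   696 718      -          2
```

Each planted hairpin is reported twice — the mature itself on one strand
and its near-complementary star-side arm on the other — exactly what a
mismatch-tolerant scan should see on a stem-loop. Fold and validate the
first candidate:

```r
hit <- hits[1, ]
win <- extract_precursor(sim$transcripts[[hit$transcript]], hit, flank = 60)
fold <- fold_mfe(win$sequence)
validate_hairpin(fold, win$mature_offset, win$mature_length)
#> stem-loop: yes (ok); arm 5p, 100% of mature paired, mfe -87.71
```

TAS detection places the cleavage site by the 10/11 rule (site at
[150, 171) → cut at 161) and tiles phased windows from the cut:

```r
tas <- generate_tas("Nat-miR390a", cat59, site_pos = 150, n_phases = 4, seed = 11)
find_tas_loci(tas$sequence, queries["Nat-miR390a"], n_windows = 4)[[1]]
#> TAS locus on TASsyn_Nat-miR390a triggered by Nat-miR390a (score 0),
#>   cleavage at 161, 4 window(s)
```

Response classification from a synthetic qPCR experiment (three planted
archetypes, 2-cycle ≈ 4-fold effects, sd 0.3 Ct, n = 3):

```r
arch <- c(miR390 = "OS-inducible", miR828 = "wound-inducible",
          miR319 = "OS-inducible-JA-dependent")
q <- generate_qpcr(arch, effect = 2, sd = 0.3, n_rep = 3, seed = 3)
classify_responses(q)[, c("gene", "induction_class", "ja_class")]
#>     gene induction_class       ja_class
#> 1 miR390    OS-inducible JA-independent
#> 2 miR828 wound-inducible JA-independent
#> 3 miR319    OS-inducible   JA-dependent
```

An induction call requires both protected-LSD significance (α = 0.05)
and a > 2-fold change; every label is traceable to the stored test
objects in `attr(result, "calls")`.

See `vignettes/mirtas-methods.Rmd` for the energy model, the statistical
conventions and the design decisions behind each stage.

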