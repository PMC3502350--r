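---
title: "Methods: conserved small-RNA discovery and herbivory-response classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved small-RNA discovery and herbivory-response classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtas)
```

# Scope

`mirtas` implements a homology-based pipeline for finding conserved plant
microRNAs and trans-acting siRNA (TAS) loci in a transcriptome, and for
classifying small-RNA responses to simulated herbivory: mismatch-tolerant
search of known matures, an ORF-based coding filter, minimum-free-energy
(MFE) hairpin folding with stem-loop validation, complementarity-based
target and TAS prediction with 21-nt phasing, neighbor-joining phylogenies
with bootstrap, and qPCR/microarray response classification into
wound-/OS-inducible and jasmonate (JA)-dependent/-independent groups.
The package ships a 59-entry *Nicotiana attenuata* mature-miRNA catalog as
its reference fixture and a synthetic-data module that generates every
input the pipeline needs, with ground truth, so all stages are testable
without external databases.

# The catalog fixture

`read_mirna_catalog()` loads the packaged catalog: name, mature sequence,
precursor MFE (kcal/mol, absent for 7 entries whose precursors did not
fold into reportable stem-loops), printed length and GC, closest homolog
and E-value. The printed length/GC columns contain internal
inconsistencies relative to the printed sequences (e.g. Nat-miR393a's
22-nt sequence against a printed length of 21). The loader deliberately
preserves both: `length_printed`/`gc_printed` are carried verbatim,
`length_nt`/`gc_percent` are recomputed from the sequence, and a
`consistent` flag marks agreement. Nothing is silently "corrected".
GC is rounded half-away-from-zero to one decimal, which reproduces the
printed column exactly on consistent rows (47.619 → 47.6). Catalog MFE
statistics are computed over recorded values only; the least-negative
recorded MFE is −33.3 and the most negative −104.3 kcal/mol.

# Homology discovery

`scan_homologs()` performs an exhaustive ungapped Hamming scan of each
20–24-nt query along both strands of every transcript (compiled code;
a full scan at these query lengths is exact and avoids seed/gap
heuristics whose parameters would be irreproducible). Coordinates are
0-based half-open on the forward strand; minus-strand hits carry a strand
flag and a query-oriented `matched_seq`. The default mismatch budget is
4; the scan threshold and the candidate filter are one configurable
maximum, since tighter search-stage settings would only remove candidates
the filter accepts.

The coding filter is a 6-frame longest-ORF heuristic
(`coding_filter()`, AUG-initiated and stop-terminated, default threshold
100 aa). It replaces protein-database homology searching, which is
version- and download-dependent; the threshold is exposed so users can
match their annotation conventions. `extract_precursor()` cuts a window
of ±100 nt (default) around a hit — published precursor structures imply
windows of roughly 70–250 nt — reverse-complementing minus-strand windows
so the mature always reads 5'→3'.

# RNA folding model

`fold_mfe()` is a Zuker-style O(n³) dynamic program over nested
structures with Watson–Crick and G:U pairs, minimum hairpin loop 3,
interior loops bounded at 30 unpaired nt, and affine multiloops. The
energy model (`rna_energy_params()`, version 1.0) consists of a 6×6
37 °C stacking table satisfying the thermodynamic symmetry
E(p₁/p₂) = E(rev p₂ / rev p₁), tabulated hairpin/bulge/internal-loop
initiation penalties with Jacobson–Stockmayer logarithmic extrapolation
(1.75·RT·ln, RT = 0.6163 kcal/mol), a length-asymmetry term for internal
loops (0.5 per nt, capped at 3), and multiloop coefficients
a = 3.4, b = 0.4 per branch, c = 0.1 per unpaired nt.

This is intentionally a *reduced* model: no dangles, coaxial stacking,
tetraloop bonuses or terminal-AU penalties. Absolute energies are
therefore not comparable to full Turner-parameter folders, and the
catalog's MFE column is treated as fixture metadata, never as a folding
target. What the reduction buys is honesty of testing: the same energy
tables drive both the dynamic program and an independent
exhaustive-enumeration oracle (all nested structures, scored by loop
decomposition), and the two agree exactly on hundreds of random
sequences up to 22 nt.

Numerical choices: energies are compared with an absolute tolerance of
1e-7; co-optimal structures are resolved deterministically by a
pairing-greedy leftmost-first traceback (prefer a paired base at the
leftmost undecided position, then the smallest partner, then
stack > interior > multiloop > hairpin). `mfe` is ≤ 0 by construction,
0 exactly when the empty structure is optimal, in which case no pairs are
reported.

`validate_hairpin()` encodes the stem-loop criteria, which published
precursor screens leave unstated and are therefore declared here rather
than inferred: (i) the structure unit enclosing the mature contains
exactly one hairpin loop; (ii) the mature lies entirely on one arm and
does not overlap the terminal loop; (iii) at least 60% of mature
nucleotides are paired; (iv) MFE ≤ −15 kcal/mol. The first failing
criterion is reported. Extra hairpins formed by flanking sequence outside
the mature's own stem-loop unit do not disqualify a candidate — windows
extracted from real transcripts routinely carry incidental structure.
Both thresholds are arguments and are echoed in the validation object.

# Targets, TAS loci and phasing

`predict_targets()` scans transcript windows against the miRNA's reverse
complement, counting Watson–Crick mismatches and G:U wobbles separately;
the score is mismatches + wobble_weight × wobbles with
wobble_weight = 1 by default (a nucleotide-level search has no wobble
concept, so the transparent default treats them alike; 0.5 gives
plant-rule-style scoring). Duplexes are ungapped — 20-nt queries under
default nucleotide-search parameters effectively yield ungapped hits.

`find_tas_loci()` locates trigger sites (canonically miR390 → TAS3,
miR828 → TAS4), places the cleavage position between the target
nucleotides paired to miRNA positions 10 and 11 — the standard
plant-miRNA-guided cleavage register, exposed as configuration since it
is a convention rather than a measurement — and tiles 21-nt phased
windows 3' from the cut. Only single-trigger phasing is implemented; the
dual-site register of some TAS3 families is out of scope and noted here.
Terminal windows shorter than the phase length are flagged truncated.

# Phylogeny

`p_distance()` computes p-distances (or Jukes–Cantor) with pairwise gap
deletion. `neighbor_joining()` is the classical Saitou–Nei algorithm
with the standard branch-length formulas, a deterministic lexicographic
tie-break on Q ties, and negative branch lengths clamped to zero with
the raw values retained in `attr(tree, "edge.length.raw")`. The primary
correctness oracle is the additivity guarantee: on distance matrices
derived from random trees, topology and all path lengths are recovered
exactly (and agree with an independent implementation).
`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate (replicate *r* seeds the generator with
seed + *r*, making runs reproducible and replicates independent), and
reports bipartition frequencies as percents in `node.label`, where they
survive Newick round-trips. Alignment construction itself is an input,
not a package responsibility.

# Expression analysis

`relative_quantity()` implements Livak 2^−ΔΔCt quantification. ΔCt is
gene minus reference (default `NaEF`) per condition; ΔΔCt subtracts the
calibrator (default WT/CTRL at the earliest time); the exponent sign is
chosen so that induction yields values above 1. Per-replicate
quantities, paired with the reference by replicate index, are emitted on
the log2 scale for downstream ANOVA — log2 both stabilizes variance and
makes the 2-fold screen an additive threshold. Missing reference cells
are hard, named errors; imputation would silently bias ΔΔCt.

`anova_plsd()` fits one-way ANOVA by the pooled sums-of-squares
decomposition and applies Fisher's *protected* LSD: pairwise pooled-
variance t tests on the error degrees of freedom, performed only when
the omnibus F is significant at α (default 0.05). The compact letter
display uses insert-and-absorb over groups in descending mean order,
with letter symbols assigned by ascending mean so the lowest group reads
"a". Because p-values are exact under normality, the omnibus type-I
error is calibrated at the nominal level (checked at 10,000 null
simulations with n = 3 per group).

`normalize_array()` divides each sample by its 75th percentile (linear
interpolation, R quantile type 7) and log2-transforms, making columns
invariant to per-sample scale factors; `fold_change_screen()` passes
genes with |mean log2 difference| strictly greater than log2(2) to the
protected LSD.

## Response classification

`classify_induction()` labels a gene OS-inducible when W+OS exceeds both
CTRL and W+W, wound-inducible when both treatments exceed CTRL without
differing from each other, and not-induced otherwise. A design decision
worth spelling out: a "difference" here requires protected-LSD
significance *and* a magnitude above log2(min_fold) with min_fold = 2 by
default. With n = 3 replicates and half a dozen pairwise tests per gene,
a pure α = 0.05 rule lets single noisy comparisons flip calls several
percent of the time — in particular the equivalence side of
JA-independence ("no WT vs ir-aoc difference") would fail by chance in
5–15% of truly independent genes. Pairing significance with a fold-change
floor is the same convention the 2-fold microarray screen uses, and it
is what makes the archetype-recovery guarantees below hold. Both α and
min_fold are arguments everywhere.

`classify_ja()` (per timepoint) calls JA-dependent when the gene is
induced in WT but not in the JA-deficient genotype, JA-independent when
induced in both with no genotype difference within any treatment,
JA-suppressed when constitutively elevated in ir-aoc (CTRL comparison),
and undetermined otherwise, in that order.

`classify_responses()` combines timepoints the way response patterns are
read in practice: a small RNA counts as inducible when it is inducible
at either harvest (OS-specificity taking precedence over plain
wounding) — some genuine responses peak at 1 h and have relaxed by 5 h.
The gene-level JA label is then derived from the combined per-genotype
induction calls plus WT vs ir-aoc contrasts per treatment that pool
replicates across timepoints; the planted contrasts are constant over
time, so pooling doubles the error degrees of freedom and stabilizes the
equivalence call. Per-timepoint labels are also reported, and every call
is traceable to the stored `plsd` objects in `attr(result, "calls")`.

# The synthetic-data module

The generators define the study conditions under which the pipeline's
guarantees are stated; they are not tuning knobs.

* **Transcriptomes** (`generate_transcriptome()`): by default 2000
  transcripts of 300–1500 nt, 50 planted precursors carrying 0–4
  substitutions in the mature, 20 coding decoys with ≥100-codon ORFs,
  everything else guaranteed ORF-free. Precursors are built as
  pad–mature–pad arms with an 8-nt loop and a near-reverse-complement 3'
  arm whose controlled mismatches never sit opposite the mature, inserted
  on a random strand. Truth records coordinates, strand and substitution
  counts.
* **Precursor sets** (`generate_precursor_set()`): 52 valid plus 7
  corrupted candidates by default, mirroring the catalog's split.
  Corruption modes: scrambled 3' arm, mature across the terminal loop,
  and a weak stem with heavy substitutions throughout the 3' arm. The
  generator folds-and-checks every candidate under the package's own
  energy model, resampling on failure, so labels are guaranteed
  independently of threshold tuning.
* **TAS transcripts** (`generate_tas()`): a planted (optionally
  mutated) trigger complement with room for the requested number of
  phased windows; truth records the site, cleavage position and window
  coordinates.
* **qPCR tables** (`generate_qpcr()`): reference Ct ~ N(20, 0.3²),
  target Ct = 24 − effect + noise, with archetype effect maps
  (wound-inducible, OS-inducible, OS-inducible-JA-dependent,
  JA-suppressed, null); the default 2-cycle effect (4-fold) and
  0.3-cycle replicate sd with n = 3 reflect routine qPCR practice.
  Baselines keep all values in the plausible 10–40 band.
* **Microarrays** (`generate_microarray()`): log-normal intensities,
  100 genes with 10 planted 4-fold changes by default, and random
  per-sample scale factors specifically so that percentile normalization
  is exercised rather than a no-op.

What the generators do *not* emulate: sequencing error models,
expression-level heterogeneity across genes, amplification-efficiency
drift, probe-level microarray artifacts, or hairpins embedded in
structured (rather than random) flanking sequence. Passing tests
demonstrate algorithmic correctness under the stated conditions, not
performance on any particular real transcriptome.

# Problem sizes and verification

The shipped test-suite and acceptance problem sizes are: exhaustive
folding-oracle comparison on 200 random sequences of ≤ 22 nt; NJ
additivity on 100 random 8-taxon matrices; discovery on one
2000-transcript database with 50 planted precursors; the 52/7 hairpin
validation split; 10,000 null ANOVA simulations; and 500 classified
archetype genes. These run in about two minutes total on one CPU and
were chosen as the smallest sizes at which the stochastic guarantees
(calibration within ±0.01, recovery ≥ 95%) are sharp.

# Known limitations

* Absolute folding energies are model-specific (see above); only
  structure-level conclusions transfer.
* The coding filter is a length heuristic; short coding ORFs (< 100 aa)
  pass as non-coding.
* Ungapped scanning misses homologs with indels, by design.
* `p_distance()`'s Jukes–Cantor option fails on saturated pairs
  (p ≥ 0.75) rather than guessing.
* Single-trigger TAS phasing only; two-hit registers are not modeled.
* The JA axis assumes genotype contrasts are stable across the profiled
  timepoints when pooling; time-varying genotype effects would dilute
  the pooled test.
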