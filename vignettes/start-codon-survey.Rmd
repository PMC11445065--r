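---
title: "Surveying non-canonical start codons in bacterial regulator genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying non-canonical start codons in bacterial regulator genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startcall)
```

## The problem

Most bacterial genes start at ATG, but GTG and TTG initiate a substantial
minority of open reading frames, at a cost: initiation from a non-canonical
codon is several-fold less efficient, so the choice of start codon is a
coarse dial on protein level. In carbohydrate-utilization regulator genes
(repressors such as *lacI*, global regulators such as *cra* and *mlc*),
lowered repressor dosage raises the basal expression of the regulated
catabolic operon and can shorten the lag when the sugar appears — a fitness
effect measurable in competition experiments. `startcall` packages the two
computational halves of such a study:

1. a **genomic survey**: locate a regulator gene in each of many genomes,
   score candidate translation initiation sites with a trainable start-codon
   plus ribosome-binding-site (RBS) model, resolve ambiguous nearby starts
   into fractional per-genome calls, aggregate them into per-regulator and
   per-genus usage percentages, and compare regulator categories
   statistically; and
2. the **competition arithmetic**: normalized competitive indices from
   selective plating, barcode loads from qPCR fractions, and
   density-normalized reporter signals.

Because the cohorts such surveys run on are tens of thousands of downloaded
genomes, the package ships a synthetic-data module that generates genome
cohorts with *planted ground truth*, so the whole pipeline is testable
end-to-end on a laptop.

## Homology localization

Each reference gene is located in a genome by an exact affine-gap local
alignment (Smith–Waterman) over both strands of every contig, replacing a
BLAST step. Scoring defaults are match +2, mismatch −3, gap open −5, gap
extend −2; a gap of length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$.
`N` bases never match. Instead of an E-value (which is meaningless without
BLAST's extreme-value statistics) a deterministic score floor is used,
defaulting to $0.6 \times \mathrm{match} \times |q|$ — about the score of a
60%-identity gapless alignment over the full query, far above random
background for queries of a few hundred nucleotides. Multiple hits per
subject are recovered by masking each reported span with `N` and
re-scanning; only the best hit per (genome, gene) enters the survey, with
ties broken deterministically (smaller start, then `+` strand, then contig
id). The kernel is a two-pass C++ routine (score-only scan, then a
traceback pass on a bounded window); an independent pure-R dynamic-program
oracle checks it exactly in the test suite.

The best hit is excised together with up to 75 nt of flanking sequence on
each side, reverse-complemented if needed so the excised window always
reads 5′→3′ in gene orientation. Candidate start sites outside this window
are invisible by construction, mirroring what the original survey fed to
its gene finder.

## The start model

The model is trained on one annotated genome (by default the undiverged
training genome the simulator emits) and has two parts.

**Start-codon weights.** $w(c) = \log\frac{n_c + 1}{N + 3}$ for
$c \in \{\mathrm{ATG}, \mathrm{GTG}, \mathrm{TTG}\}$, the add-one-smoothed
log-frequency of codon $c$ among the $N$ annotated starts. Training
requires at least 50 usable genes (annotated start with ≥ 16 nt of
upstream context).

**RBS table.** For every k-mer length $k \in \{3,\dots,6\}$ and spacer
$s$ (distance in nt between the k-mer 3′ end and the start codon, binned
into $[3,5), [5,7), [7,9), [9,11), [11,13), [13,16)$), the table holds

$$\mathrm{lo}(m, b) \;=\; \log \frac{P(m \text{ at a spacer in } b \mid
\text{true start})}{P(m \mid \text{background})},$$

with add-one smoothing over the $4^k$ k-mers per (k, bin) cell and an
i.i.d. background from the training genome's nucleotide composition. A
candidate's `rbs_score` is the maximum of $\mathrm{lo}$ over all k-mers
and spacers available in its upstream context; `rbs_present` is
`rbs_score >= rbs_present_threshold`.

**Why the RBS-present threshold is 1, not 0.** "Above background" (0)
sounds natural, but the score is a *maximum over roughly forty lookups*,
and under add-one smoothing the chance-level maximum for a motif-free
upstream sits around +0.35: with threshold 0 essentially every candidate
would count as RBS-positive and the RBS-consistency rule below would never
fire. The default of 1 log-odds unit clears that chance level by a wide
margin while staying far below the score of a planted Shine–Dalgarno motif
(≈ 3–4 under the default training conditions). The threshold is a model
field and can be changed at training time.

Models serialize to versioned JSON (`write_start_model()` /
`read_start_model()`).

## Candidate enumeration and fractional resolution

Within the flanked region, every ATG/GTG/TTG in the reading frame of the
homology hit, downstream of any upstream in-frame stop and upstream of the
shared closing stop, is a candidate; all candidates share that stop. The
frame is anchored at `hit_offset - qstart`, so an alignment that clips the
query's 5′ end still indexes the gene's codon lattice. An overlapping
out-of-frame ATG (as in an `ATGTG` configuration) is *not* a candidate —
it lies in a different frame.

Ambiguity is resolved by three rules:

1. **Length**: drop candidates whose ORF spans less than 90% of the hit
   length (fragmented proteins are unlikely to be functional).
2. **Score ratio**: keep candidates whose total score (RBS + start weight)
   is within 80% of the best survivor. A ratio rule is ill-defined for
   negative log-odds scores, so all scores are first shifted by
   $-\min(0, \min \mathrm{score}) + \varepsilon$; on already-positive
   scores the shift is the negligible $\varepsilon = 10^{-9}$ and the rule
   reduces to the plain 80% cut.
3. **RBS consistency**: if the top survivor has a predicted RBS, drop
   alternatives that do not.

Each of the $k$ retained candidates contributes $1/k$ to its codon class:
three retained starts ATG, GTG, GTG count as 2/3 GTG and 1/3 ATG. The call
object stores the integer class counts and $k$ (so normalization is exact
as rationals); derived double weights are reported at full precision in
machine output and *truncated* (not rounded) to two decimals in
human-readable reports — 0.66 and 0.33 for the example above. The order of
rules 1 and 2 is configurable (`rule_order`); they coincide on typical
candidate sets, where everything near the planted start is length-valid,
and the default applies length first.

```{r example}
sc <- data.frame(pos = c(0, 3, 9), codon = c("ATG", "GTG", "GTG"),
                 stop_pos = 300, orf_length = c(303, 300, 294),
                 frame_anchor = 0, rbs_score = 5, rbs_present = TRUE,
                 start_score = 0, total_score = 5, truncated = FALSE)
resolve_starts(sc, hit_length = 300, gene = "lacI")
```

## Cohort aggregation and statistics

`qc_filter()` applies the survey's genome-quality rules: completeness
≥ 95%, contamination not *larger* than 10% (10.0 passes), a contig-count
cap (default 200), and a size rule excluding genomes smaller than their
species median minus three scaled MADs — the survey's "exceptionally
small" criterion made explicit, since no number was given. Scaled MAD
(consistent with the SD under normality) keeps the rule comparable to a
3-sigma cut. `subsample_genera()` discards genera under 10 genomes and
caps large genera at 100 by seeded uniform subsampling.

`aggregate_usage()` averages per-genome fractional calls with equal genome
weight and reports percentages per codon class; rows sum to 100 within
1e−9. Because it is not obvious whether a headline figure like "99%
non-canonical" should weight ambiguous genomes fractionally or by their
majority call, both are reported (`non_atg_percent` fraction-weighted, the
default reading, and `majority_non_atg_percent` alongside).

`mann_whitney_u()` is implemented in the package: exact two-tailed p by
complete enumeration when $n_1 + n_2 \le 12$ without ties, otherwise the
normal approximation with tie correction and continuity correction. Tests
cross-check it against a pairwise-counting permutation oracle and against
`stats::wilcox.test`. `compare_categories()` applies it to per-regulator
non-ATG percentages split by category, and per regulatory mode when modes
are available.

`fitch_parsimony()` counts minimum state changes on a supplied rooted tree
(polytomies resolved deterministically; unrooted input is
midpoint-rooted, and monophyly statements are conditional on that
rooting). `is_state_monophyletic()` asks whether the genomes carrying a
codon state form one clade; a state that is *not* monophyletic implies
multiple independent origins of that start codon.

## Competition arithmetic

With two-strain selective plating, the WT load is
$\mathrm{cfu_{WT}} = \mathrm{cfu_{total}} - \mathrm{cfu_{mutant}}$ (a
mutant count above the total is a counting inconsistency and errors). The
normalized competitive index is

$$\mathrm{C.I} = \frac{\mathrm{cfu_{mutant}} / \mathrm{cfu_{WT}}}
{\mathrm{inoc_{mutant}} / \mathrm{inoc_{WT}}},$$

1 being fitness-neutral. Zero mutant counts give C.I 0 with a
`below_detection` flag (a pseudocount mode exists but is off by default —
plotting such points at the axis floor, flagged, is the honest default);
zero WT counts are undefined and flagged. Group summaries use medians, and
group comparisons reuse the package's Mann–Whitney test with the usual
significance bands (NS / \* / \*\* / \*\*\* at 0.05 / 0.01 / 0.001).
Barcode loads are `rel_density * cfu_plate`; reporter signals are
`(fluorescence - autofluorescence) / OD`, floored at 0 with a flag. The
autofluorescence control is a required explicit input rather than being
inferred from blanks.

## The synthetic cohort generator

`generate_cohort()` emulates a cohort of conspecific genomes: an i.i.d.
background contig at a configurable GC content (GC is a free parameter of
the simulation, not a claim about any species), with each regulator locus
planted once — Shine–Dalgarno motif at a chosen spacer, chosen start
codon (optionally varying per genome), optional in-frame secondary start
within ten nucleotides, optional overlapping out-of-frame `ATGTG`
configuration whose ATG frame terminates within five codons. Genome 0 is
emitted undiverged with a GFF3 annotation and serves as the training
genome; the others are derived by i.i.d. point substitutions at the
configured divergence rate.

Two realism choices matter:

* **Masking.** Planted starts, stops, SD motifs and secondary starts are
  masked from divergence by default (switchable), so caller accuracy is
  measured separately from signal destruction.
* **Purifying selection.** A substitution that would create an in-frame
  stop inside a planted ORF is reverted. Without this, 5% divergence on a
  300 nt gene would truncate a sizeable fraction of planted ORFs — but
  real cohorts of functional regulators do not accumulate nonsense
  mutations, and the survey's length rule would otherwise measure simulated
  pseudogenization rather than caller behaviour.

What the generator does **not** emulate: indels, recombination,
codon-usage bias, horizontal transfer, assembly error, or sequencing
reads. Passing tests therefore demonstrate correctness of the pipeline's
logic under point divergence with intact signals, not robustness to
structural variation; the divergence masking switch exists precisely to
probe the latter.

`generate_tree()` emits rooted binary newick trees over the genomes
(random, or grouped by state to construct monophyletic cases);
`generate_competition()` simulates pairwise mutant-vs-WT platings whose
output ratio is `true_ci x inoculum ratio` under mean-1 multiplicative
log-normal noise, so the noise-free round trip recovers `true_ci` exactly
and the expected C.I equals `true_ci` at any noise level. Metadata
defaults are clean (completeness 100, contamination 0, one contig) so that
QC behaviour is tested by explicit overrides, not incidentally.

All generator outputs are byte-identical for identical configuration and
seed.

## Worked example

A small survey: train on a 60-gene genome, then call a GTG regulator
across a diverged cohort.

```{r pipeline}
codons <- rep(c("ATG", "GTG", "TTG"), c(48, 7, 5))
genes <- lapply(seq_len(60), function(i) {
  planted_gene(sprintf("tg%02d", i), orf_length = 210,
               start_codon = codons[i],
               sd_spacer = rep(c(5, 6, 7, 8, 9, 10, 13), length.out = 60)[i])
})
training <- generate_cohort(simulation_config(seed = 4242, n_genomes = 1,
                                              contig_length = 25000,
                                              genes = genes))
model <- train_start_model(training$genomes[[1]], training$annotation)

cohort <- generate_cohort(simulation_config(
  seed = 99, n_genomes = 12, contig_length = 2000,
  genes = list(planted_gene("lacI", 300, "GTG")), divergence_rate = 0.03))
calls <- call_cohort(cohort, cohort_references(cohort), model)
aggregate_usage(calls)
```

## Numerical choices and problem sizes

* Alignment tie-breaks prefer the smaller subject end, then the smaller
  query end; hit tie-breaks the smaller start, `+` strand, then contig id.
  Score ties in resolution retain both candidates — they fractionate.
* Weights are exact integer counts divided once by $k$; sums are checked
  exactly on counts and to 1e−12 on doubles.
* The exact Mann–Whitney path switches to the normal approximation above
  $n_1 + n_2 = 12$ or at the first tie.
* Test and acceptance cohorts use 200 genomes x 2 kb contigs for recovery
  checks (one 300 nt regulator, ≤ 5% divergence) and 10 genomes x 16 kb
  contigs for the 20 + 20 regulator category comparison — sizes chosen so
  the planted rates pin cohort percentages within a fraction of a
  percentage point while the full suite stays desk-scale.

## Limitations

* The start/RBS scorer is a deliberate simplification of a
  self-training gene finder; its scores are *not* numerically comparable
  to Prodigal's, so percentage thresholds (the 80% rule) are calibrated to
  this model's score scale, not transferable to another's.
* The score floor is not an E-value; it controls sensitivity through the
  query length only.
* Only ATG/GTG/TTG are ever proposed as candidates; rarer initiators
  (ATT, CTG) fall into the `other` class only if present in external
  annotation-derived tables, never from this caller.
* Monophyly conclusions are conditional on the supplied rooting.
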