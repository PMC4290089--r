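---
title: "Detecting syntenic gene losses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting syntenic gene losses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synloss)
```

## The problem

Comparative screens for lineage-specific gene loss start from a deceptively
simple observation: when one-to-one orthologs of two well-assembled
reference genomes (say, a lizard and human) are laid side by side in
chromosomal order, genes missing from a third lineage (say, birds) are not
scattered at random — many of them sit in *runs* of consecutive orthologs
that are syntenic in both references. A run of several adjacent conserved
genes that no focal genome contains is very unlikely to be an assembly
artefact, because the corresponding reference segment is large (tens of
kilobases) and its flanks are present and well placed. `synloss`
implements this screen as a reusable, testable pipeline:

1. **screen** – find candidate missing genes from a multi-species
   ortholog table and reconcile them with alignment evidence;
2. **blocks** – cluster candidates into syntenic deletion blocks, verify
   the blocks in the second reference ordering, and classify how the
   flanking segments were rearranged in the focal genome;
3. **stats** – ask whether losses cluster on particular chromosomes and
   whether the missing set is biased towards short or fast-diverging
   genes;
4. **enrichment** – compare functional annotations of the missing set
   against block-structure-matched random control sets, with
   Benjamini–Hochberg false-discovery control, and classify enriched
   terms across species contexts;
5. **synth** – a seeded simulator that plants deletions, rearrangements
   and annotation enrichments so every stage can be validated against
   known ground truth.

## Data model

The central object is the `ortholog_tbl`: one row per gene of the
*defining* species, with BioMart-style per-species columns
(`<species>_id`, `_chr`, `_start`, `_end`, `_strand`, `_placed`,
`_class`). Coordinates are 1-based inclusive (Ensembl convention) and all
spans are computed as *end − start* of the run's outermost genes.
Chromosomes sort in a canonical order — placed chromosomes natural-sorted
(`2` before `10`, then alphabetic names such as `X` or `LGf`), unplaced
scaffolds last, lexically — so every downstream result is reproducible.
Orthology classes follow the Ensembl vocabulary; *apparent one-to-one* is
pooled with strict one-to-one throughout, because the screen's reference
set pools them too.

## The screen

`identify_candidates()` restricts the table to genes with a (possibly
apparent) one-to-one ortholog between the two reference species and flags
genes with no ortholog of any class in any focal species. "Found in the
focal lineage" means present in at least one focal species; the
per-species presence matrix is kept so that, e.g., ratite-only genes can
be reported. The counts obey
`n_candidates = n_reference_1to1 − n_with_focal_ortholog` by
construction.

Manual curation is modelled as a `curation_ledger()`: an ordered list of
signed adjustments (genes recovered from other databases, misannotations,
newly recognised loci) whose running total may never go negative.
`apply_curation_ledger()` returns the closing count plus the full audit
trail.

Alignment evidence enters through `classify_alignment_hits()`. Hits with
score ≤ 50 are discarded — the cutoff is a strict "greater than 50" rule.
A surviving hit whose reciprocal best alignment returns the query locus
is accepted as the ortholog (`found_in_focal`); a reciprocal best landing
on another gene marks a family member or paralog; a hit on an unplaced
segment without synteny support is `unresolved_unplaced` and, following
the screen's conservative convention, `screen_hits()` removes such genes
from the missing list by default (they *might* be present). Verdicts are
invariant to hit order.

## Block criteria and tiers

`detect_missing_blocks()` scans one species' gene ordering for maximal
runs of consecutive missing genes. Runs never cross chromosome
boundaries, and any intervening gene present in the focal lineage breaks
a run — adjacency means consecutive rows of the one-to-one ortholog
alignment, because that is the structure the screen actually inspects. A
run qualifies as a block in one of three confidence tiers:

| tier | criterion | default |
|---|---|---|
| `multi_gene` | at least `min_block_genes` adjacent genes, unconditionally | 3 genes |
| `large_singlet_or_doublet` | 1–2 genes spanning at least `min_block_span` | 80,000 bp |
| `small_doublet` | 2 genes spanning at least `doublet_min_span` | 34,000 bp |

The 34 kb doublet rule is stated in the source screen only as an
approximate *average*; whether it was applied per doublet or as a mean is
not recoverable, so it is implemented as a per-doublet minimum
(configurable), and tiers are always reported so users can restrict
analyses to the strict ≥3-gene / ≥80 kb definition.

Non-qualifying runs are not all discarded: those within `near_block_gap`
present genes of a qualifying block (default 5; the source material
reports "close proximity" without a number) are kept as *near-block*
genes, mirroring the screen's separate tally of losses adjacent to
blocks. Everything else is dropped from block output.

`refilter_blocks()` repeats the verification in the second reference
ordering: a block whose members stay contiguous on one chromosome there
is `verified_in_both`; a block split by an intervening present gene is
partitioned into maximal second-species runs, and each part is re-tested
against the criteria using its gene count and its span in *both*
species (re-applying the criteria after realignment is the point of the
step; requiring both spans keeps tiers consistent in the defining
species). Parts that fail are demoted to the near-block list. Members on
unplaced second-species scaffolds cannot be verified, so their block is
retained with `verified_in_both = FALSE`. The operation is idempotent.

`classify_flanking_rearrangements()` compares the two reference genes
immediately flanking each deleted run with their arrangement in the focal
genome, with precedence: `unresolved` (flank absent/unplaced) →
`different_chromosome` → `same_chr_reversed` (both flanks strand-flipped,
the signature of an inversion) → `same_chr_reordered` (order swapped
without the flip) → `same_chr_distant` (separation above
`distant_flank_bp`) → `colinear`. The "several megabases apart" language
of the source screen is made concrete as a 5 Mb default, exposed in
`loss_thresholds()`.

## Chromosomal distribution and size bias

`chisq_uniformity()` tests per-chromosome counts against a weighted
expectation — chromosome length, gene count, ortholog count, or an
empirical baseline averaged over ten seeded random draws of equal-sized
gene sets (`random_set_weights()`). Although the original analysis calls
this a chi-squared test of independence, with a single observed vector it
is a goodness-of-fit test and is implemented as one: expected counts are
`total × wᵢ/Σw`, the statistic is `Σ(O−E)²/E` with no continuity
correction, and `df = k − 1` (23 human chromosomes give df = 22, matching
the printed degrees of freedom). Unplaced scaffolds are pooled into a
single `"Un"` category (`chromosome_counts()`), as in the screen's
distribution plots. A warning is emitted when any expected count falls
below 5.

Paired block sizes across the two references are compared with a
hand-written Wilcoxon matched-pairs signed-rank test: zero differences
dropped, midranks for ties, exact two-sided p by full enumeration of the
2ⁿ sign assignments for n ≤ 12 (the enumeration remains valid under
ties, where the classical exact distribution does not apply), and a
tie-corrected normal approximation without continuity correction for
larger n.

`size_bias_report()` covers the "are we just missing short, fast genes?"
control: a one-way ANOVA on log CDS lengths of missing vs retained
genes, short-gene fractions below 500 bp, and the correlation between
CDS length and cross-species percent amino-acid identity within the
missing set. Pearson is the default because the diagnostic looks for a
linear trend; Spearman is available.

## Matched controls and permutation inference

The null model for functional enrichment is not "274 random genes" but
"274 genes organised like the missing set": `generate_control_sets()`
draws, for each required block of N genes on a given chromosome, a random
run of N consecutive one-to-one orthologs on that chromosome that is
colinear in both references (one second-species chromosome, monotone
coordinates), optionally matching the block span within ±20%
(`span_tolerance`; the source screen says "same relative size" without a
number). Control blocks never overlap the missing set when an exclusion
list is supplied and never overlap each other within a set by default.
Draws use R's Mersenne–Twister generator under a fixed seed, so the same
seed reproduces the same sets byte for byte.

`permutation_test()` compares the observed annotation burden with its
distribution over control sets. The set-level statistic is the number of
genes carrying at least one term; per-term statistics count carriers of
each term. Two-sided p-values double the smaller tail with the add-one
correction `(b + 1)/(n + 1)`, capped at 1 — so `p ≥ 1/(n+1)` and the test
is slightly conservative, the standard behaviour for sampled permutation
nulls. When the caller supplies the *complete* enumeration of control
sets (`exhaustive = TRUE`), tail probabilities are exact proportions and
the add-one correction is dropped. Per-term p-values receive
Benjamini–Hochberg correction across all tested terms. For
phenotype-source annotations the catch-all term labelled "No abnormal
phenotype detected" is excluded from every statistic.

Two numerical consequences of this formula are worth recording. First,
with n permutations the smallest attainable two-sided p is 2/(n+1), so a
Benjamini–Hochberg family of m terms can only reach `q < 0.05` when
`m · 2/(n+1) < 0.05`; with 1,000 permutations that means m ≤ 25. The
package's power checks therefore use a 20-term family. Second, because
the statistic is integer-valued, the achieved size of the test sits
below the nominal α unless the null statistic is spread over many values;
calibration checks use a universe of 5,000 genes and sets of 500 so the
null has enough resolution for the nominal and achieved levels to agree,
and reject at `p ≤ α`.

`fisher_term_enrichment()` performs the per-species two-tailed Fisher's
exact test of term membership against a gene universe (the classical
hypergeometric summation over tables no more probable than the observed
one, via `stats::fisher.test`). The `enriched` flag is a pure `p < α`
threshold, with a `direction` column separating over- from
under-representation; terms with no carrier in the background are
skipped and recorded.

`venn_group_classify()` maps the seven regions of the
chicken/human/lizard enrichment Venn diagram onto interpretation groups:

| region | group | reading |
|---|---|---|
| human only; human ∧ lizard | A | disruption only outside birds — plausibly compensated in birds |
| chicken only | B1 | disruption only in the avian context |
| chicken ∧ human; all three | B2 | no apparent compensation anywhere |
| lizard only; chicken ∧ lizard | C | sauropsid-specific disruption |

This truth table keeps every region consistent with the narrative
definition of Group C ("enriched in chicken and lizard or lizard only but
not humans"), which the figure legend abbreviates. When a gene carries
enriched terms from several groups, the screen's manual rule is applied:
descriptively similar terms send the gene to the most species-inclusive
group (B2 ≻ A ≻ C ≻ B1); dissimilar terms list the gene in every group.
Similarity is a user hook; the default (exact term identity) is a
stand-in for ontology-aware ancestor matching, not a claim of
equivalence.

## The simulator and what passing tests mean

`simulate_ortholog_tables()` emits two reference species sharing gene
order and a focal species from which planted blocks and optional random
singleton dropouts have been deleted. Gene and intergenic lengths are
log-normal; reference genes default to a 20 kb median and focal genes to
a compact-genome 10 kb median, with 10 kb median intergenic gaps — round
values in the range typical of amniote gene loci, chosen once and fully
configurable. Deletions are planted non-overlapping with a one-gene
buffer so each planted block is a distinct maximal run; rearrangements
(inversion, transposition, translocation, one optional event per
chromosome and type) are applied to the focal lineage *after* deletion,
so flanking-rearrangement calls have planted truth; a configurable
fraction of focal genes is relocated to unplaced scaffolds.
`simulate_annotations()` plants term enrichments as relative risks on a
baseline carrier probability.

The simulator emulates the *structure* the pipeline exploits — runs of
missing one-to-one orthologs, conserved order across references,
rearranged or unplaced flanks, annotation enrichments. It does not
emulate assembly gaps, annotation error, lineage-specific duplication,
many-to-many orthology, or sequence divergence; recovery of planted
blocks with precision and recall 1 therefore demonstrates the
correctness of the detection logic under clean input, not the field
performance of the screen on real genomes, which depends on curation
steps that are intrinsically manual.

```{r, eval = FALSE}
spec <- genome_sim_spec(seed = 7)
report <- run_full_pipeline(run_config(spec))
report$counts
glance(report$blocks)
autoplot(report$chrom_dist$lizard)
```

## Validation suites and problem sizes

The test suite validates each operation against an independent oracle:
exhaustive maximal-run enumeration for block detection (1,000 random
instances of up to 50 genes), full sign-assignment enumeration for the
signed-rank test, hypergeometric enumeration for Fisher, a step-up
re-derivation for Benjamini–Hochberg, closed-form sums of squares for
the ANOVA, and exact subset enumeration for the permutation test on a
five-gene universe. Calibration is measured over 1,000 simulated null
data sets (universe 5,000, sets of 500, 999 permutations each) and
planted-enrichment power over 50 replicates (relative risk 5, 50-gene
target, 1,000 permutations). These sizes keep the whole suite within a
few minutes on one core while leaving each check statistically
informative.

## Known limitations

* The screen's manual curation (database cross-checks, expert reading of
  hits) is represented only by its decision rules; the package cannot
  reproduce judgment calls.
* Orthology classes are taken as given; the pipeline does not infer
  orthology from sequence.
* `refilter_blocks()` treats a second-species run interrupted by another
  *missing* gene (from a different block) as contiguous; only present
  genes break runs.
* The empirical-random expectation mode averages integer counts over a
  small number of draws (default 10), so its weights are themselves
  noisy; it is faithful to the original procedure rather than optimal.
* Span matching for control sets can make tight requirements
  unsatisfiable on short chromosomes; the generator fails loudly naming
  the requirement rather than silently relaxing it.
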