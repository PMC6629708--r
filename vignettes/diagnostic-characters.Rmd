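---
title: "Diagnostic DNA characters, barcode distances and clade support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic DNA characters, barcode distances and clade support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(synapodiag)
```

## The problem

Modern descriptions of higher taxa (for instance new subfamilies of
Hesperiidae, the skipper butterflies) increasingly rest on two kinds of
molecular evidence: *diagnostic nucleotide characters* — alignment
positions where every sequenced member of a clade carries one state while
the outgroups carry another — and *multi-tree bootstrap support* showing
that the clade is a deep, well-separated lineage even when its exact
placement is unresolved. A third, smaller task recurs alongside them:
associating specimens (for example, the two sexes of a dimorphic species,
or a century-old type) by COI barcode distance.

synapodiag implements that workflow end to end on partitioned exon
alignments: a seeded simulator with planted ground truth, the
synapomorphy scan and its ranking, the compact character notation, barcode
p-distances with single-linkage specimen grouping, NJ trees with
column-bootstrap support, and the rank rule.

## The synapomorphy rule

For a focal clade $F$ and outgroup set $O$, a column of the alignment is
a candidate *derived* character $a \rightarrow d$ when:

1. every non-missing state in $F$ equals $d$ (missing symbols `N`, `-`,
   `?` and IUPAC ambiguity codes never break invariance but are counted);
2. the modal outgroup state $a$ has frequency $\ge$
   `outgroup_majority_threshold` among non-missing outgroup states
   (the "mostly invariant" outgroup);
3. $a \ne d$; and
4. with `forbid_derived_in_outgroup = TRUE`, no outgroup taxon carries
   $d$ at all.

When the clade is invariant and its state is absent from every observed
outgroup state yet no single outgroup state qualifies as a majority, the
ancestor cannot be polarized and the column is reported as a
`state_only` character (rendered as bare position + state, e.g. `474C`).

Candidates are ranked the way printed diagnoses were chosen: smallest
number of focal taxa with missing data first, then the highest minimum
read depth across focal taxa (weakest-link coverage), then locus order
and position; the top `top_k` (default 6, the typical length of a
printed list) are reported.

Two quantities in the rule are genuinely open choices, since "mostly
invariant" and "higher coverage" are qualitative descriptions:

* `outgroup_majority_threshold` defaults to **0.9**, with the leak-ban
  (clause 4) on by default. This is deliberately strict: a diagnostic
  character that recurs in outgroups is useless for identification.
  The leak-ban is checked before the majority clause, so a column whose
  derived state appears in the outgroup is rejected for that reason even
  when the outgroup is too variable to name an ancestor.
* the coverage tie-break uses the *minimum* depth over focal taxa with
  data at the position. A mean would let one deeply covered taxon mask a
  barely covered one; the minimum is the depth of the weakest observation
  supporting the character. Masked taxa (depth 0 by construction) are
  excluded — they are already penalised through `missing_count`, which
  dominates the ranking.
* `max_focal_missing` defaults to clade size minus one, i.e. any column
  with at least one observed focal state competes, and the ranking sorts
  the reliable ones first. Tightening it turns the soft penalty into a
  hard filter.

### Clades with a single sequenced member

A clade represented by one specimen cannot show invariance. The scan
then unites two sources (`scan_singleton()`): positions where the
*sister* clade carries a synapomorphy $a \rightarrow d$ while the focal
taxon retains $a$ — reported as retained characters, rendered
`A548A (not C)` — and ordinary derived synapomorphies of the parent
clade (focal plus sister) against a wider outgroup. Positions where the
focal taxon is missing, shares the sister's derived state, or shows a
third state contribute nothing. Retained characters of `state_only` kind
are not constructed: without a polarized sister ancestor there is no
"not X" statement to make.

## Character notation

Characters are exchanged as compact strings:
`aly728.44.1:G672C` is position 672 of exon 1 of gene 44 on scaffold 728
of the reference genome tagged `aly`, changed from ancestral G to C;
`aly499.37.1:G77G (not A)` is a retained ancestral G where the sister
clade changed to A; prefix-free strings (`C235T`, `474C`) address the
standard 658-bp COI barcode, so their positions never exceed 658. The
codec (`parse_characters()` / `render_characters()`) is bit-exact in both
directions; the digits inside a notation string are authoritative for the
position. Any lowercase prefix is accepted, so genomes other than `aly`
can be addressed. A bare position + state string always parses as a
barcode character; an unpolarized character on a nuclear exon keeps its
locus prefix (`aly728.44.1:169A`) so that parsing inverts rendering for
every character. `inst/extdata/hesperiidae_diagnoses.txt` carries the 30
published diagnosis strings of Katreinae, Chamundinae and Barcinae as a
round-trip fixture.

## Barcode distances and specimen association

`p_distance()` is the uncorrected proportion of differing sites, counted
only where both sequences have an unambiguous base, reported with its
bookkeeping (`n_compared`, `n_diff`) and a display percentage rounded
half-up to one decimal — 58 differences over the full 658-bp barcode
print as 8.8%. No substitution-model correction is applied because
published comparisons quote raw base-pair differences. The same raw
distance feeds tree building, keeping the two modules consistent.

`associate_specimens()` groups specimens by single-linkage at a
p-distance threshold, default **0.02**. The empirical contrast this
mirrors is stark — conspecific barcodes a single base pair apart
(~0.15%) versus heterospecific ones at 8.8% — so any threshold between
those extremes yields the same groups; 2% is the conventional figure for
Lepidoptera barcodes. Between-group minimum distances are reported so a
borderline threshold is visible in the output.

## Trees and the rank rule

Tree estimation here is deliberately light: neighbor joining on
p-distances with support from resampling alignment columns with
replacement (`bootstrap_support()`, seeded, bit-reproducible). The
package's contribution is the support *logic*, not likelihood inference;
NJ on additive matrices is exact, which the tests exploit as an oracle,
and maximum-likelihood programs remain the right tool for real matrices.

`rank_decision()` encodes the argument used to justify subfamily rank
when placement is uncertain. It takes a support report over several
trees (typically nuclear, Z and mitogenome partitions) and two kinds of
reference clades: an *inclusion* clade the focal lineage belongs to and
an *exclusion* clade it falls outside of. The recommendation is
`subfamily` iff both reference clades reach `strong_threshold` (default
**95**, between the 89% and 97% that published discussions treat as weak
and strong) in *every* tree, the inclusion clade contains the focal taxa
and the exclusion clade does not. The focal clade's own placement
support is irrelevant: whichever of the possible placement scenarios
holds, the lineage is confined between the two reference clades and is
its own deep branch. Degrading either reference clade in any one tree
withdraws the recommendation. Relative divergence times, which the
verbal argument also invokes, are not modelled — only topology and
support are used, a known limitation.

## The simulator and what passing tests mean

`simulate_dataset()` produces the benchmark everything else is tested
against: a pure-birth tree in which the focal clade is made monophyletic
by construction (a Yule backbone with the clade subtree grafted at a
placeholder tip), exon loci evolved independently under JC69 or GTR
(branch lengths scaled by `subst_rate`), `n_planted` synapomorphies
*overwritten* into the alignment (every clade taxon set to a derived
state, every other taxon to a distinct ancestral state) so ground truth
is exact, then per-cell Bernoulli masking and negative-binomial coverage.
Unmasked depth is drawn as $1 + \mathrm{NB}(\mu = \texttt{coverage\_mean}
- 1, \texttt{size} = \texttt{coverage\_dispersion})$, guaranteeing depth
$\ge 1$ with mean exactly `coverage_mean`; masked cells have depth 0.

Default study conditions are 12 taxa with a 4-taxon focal clade, 20 exon
loci of 300 bp plus one 658-bp barcode locus, 10 planted exon characters
and 3 barcode ones, 5% missing data, mean coverage 20 with dispersion 5,
and `subst_rate = 0.1` (a tree depth of a few tenths of a substitution
per site — divergent but far from saturation). Loci are split roughly
60/20/20 across the nuclear, Z and mitochondrial partitions. Clade size
is left as a free parameter: how many sequenced members make a character
trustworthy is a judgement the scan does not make for the user.

Two deliberate simplifications matter for interpreting green tests.
First, planting overwrites states rather than constraining the
substitution process, so recall against the planted list is a test of
the scanner, not of evolutionary realism. Second, with any positive
substitution rate the tree itself generates *genuine* synapomorphies on
the focal stem; these are correct detections that are absent from the
planted list. Recovery benchmarks that require zero false positives are
therefore run with `subst_rate = 0`, isolating scanner behaviour; the
companion invariant — planted characters are always a *subset* of a
strict scan's report when nothing is masked — is tested with evolution
switched on. The generator has no indels, no rate heterogeneity across
sites, no read-level errors and no correlated missingness, so passing
tests certify the algorithmic contract, not robustness to every artefact
of real assemblies.

All randomness descends from one integer seed (per-locus streams use
`seed + locus index`; the masking, planting and bootstrap stages use
fixed large offsets), which makes every output — including bootstrap
supports — bit-reproducible.

## Numerical and degenerate-input choices

* Coordinates are 1-based and closed within each exon, matching the
  notation; concatenated matrices carry an offset table whose mapping to
  (locus, position) pairs is a tested bijection.
* Ties in the outgroup state count cannot straddle the majority
  threshold (which must exceed 0.5); when no state qualifies the column
  can only be `state_only` or rejected.
* Columns that are all-missing on either side are *uninformative*,
  distinguished from rejections in the audit table that accompanies
  every scan.
* `p_distance()` refuses pairs with zero comparable sites rather than
  returning 0/0.
* NJ requires at least three taxa; three taxa yield the closed-form
  star lengths. Zero-variation alignments produce identical replicates,
  hence equal support on every node.
* `associate_specimens()` uses strict inequality (`< threshold`), so a
  threshold of 0 puts every specimen in its own group.

## A worked run

```{r, eval = FALSE}
cfg <- demo_config(seed = 1)
res <- run_pipeline(cfg, "demo_run")
res$decision
glance(res$groups)
autoplot(res$chars)
plot_support_report(res$report)
```

The run directory contains the simulated dataset (FASTA + manifest +
coverage + truth + true tree), the ranked character lists and audit
tables, the barcode distance matrix and specimen groups, three newick
trees with bootstrap labels, the support report and a JSON summary.
Problem sizes throughout the package's tests (a few thousand alignment
columns, tens of bootstrap replicates in smoke tests, one hundred in the
benchmark) were chosen as the smallest at which the statistical checks
— binomial bands around the masking fraction, saturation limits,
bootstrap concentration — are sharp.
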