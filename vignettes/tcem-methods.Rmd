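---
title: "Scoring T cell exposed motifs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring T cell exposed motifs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcemr)
library(dplyr)
```

## The scientific question

CD8+ T cells recognise HLA class I bound peptides through a short stretch of
residues — the T cell exposed motif (TCEM) — that contacts the TCR CDR3 loop:
positions 4–8 of a 9-mer or 5–9 of a 10-mer. Because the T cell repertoire is
shaped by positive selection on *self* peptides presented by cortical thymic
epithelial cells (cTECs), a nonself motif can only be recognised if T cells
specific for it (or for a sufficiently similar motif) survived selection on
some self motif. `tcemr` operationalises this idea: it scores every pentamer
motif on three attributes that proxy its ability to mediate positive
selection, and provides the downstream statistical machinery to relate those
attributes to peptide immunogenicity, naive-repertoire content, pathogen
proteome composition and HLA disease associations.

The three attributes are:

1. **Proteome frequency** — the number of 9-mer windows of the reference
   proteome whose TCEM equals the motif. An occurrence is a *window*, not a
   raw 5-mer substring hit: a pentamer within 3 residues of the N terminus or
   1 residue of the C terminus has no complete 9-mer context and is not
   counted. Motifs occurring fewer than 4 times are classified *rare*; such
   motifs are unlikely to be presented on the cTEC surface at all.
2. **cTEC expression** — per gene, the median RPKM across cTEC samples after
   TMM normalization; per motif, the median over one value per occurrence
   (a motif found k times in one protein contributes its gene's value k
   times). The relationship with immunogenicity is expected to be *bimodal*:
   unexpressed motifs cannot mediate selection, while very highly expressed
   (housekeeping-dominated) motifs are suppressed by tolerance.
3. **Proteasomal cleavage** — a per-motif score for the chance that the
   thymoproteasome (or, as a negative control, the immunoproteasome)
   liberates peptides exposing the motif.

## The cleavage cascade

The cleavage model is a four-stage cascade built on empirical digestion
preferences:

* **Preference scores.** For each position $i \in \{-5..-1, +1..+5\}$ around
  a cleavage site and residue $j$, $c_{ij}$ is the observed prevalence of $j$
  at $i$ divided by the prevalence of $j$ in the digested substrates. A
  preference table identical to its background gives $c_{ij} \equiv 1$.
* **Site scores.** The score $C$ of the bond between residues $s$ and $s+1$
  is the *median* of the $c_{ij}$ of the residues at the ten flanking
  positions. Within five residues of a terminus the median runs over the
  available positions only (at least six values at site 1); a
  `require_full_context` switch masks such sites instead.
* **Formation scores.** A 9-mer starting at $p$ requires cleavage at sites
  $p-1$ and $p+8$; its score $\bar C$ is the mean of the two. Windows at a
  protein terminus lack an interior flanking site and are excluded by
  default — a free terminus needs no cleavage, and assigning it a score
  would be unfounded. The alternative reading (terminus behaves as an
  already-cleaved site, $C = 1$) is available via `terminal = "cleaved"`.
* **Motif scores.** A motif's score is the median $\bar C$ over the windows
  whose TCEM it is, computed separately per proteasome type.

Uniform preferences propagate to motif scores of exactly 1 through all four
stages, which the test suite asserts exactly; the thymo and immuno cascades
differ only in their input table.

## Stratification conventions

Several analyses split motifs into groups; the boundaries are pinned for
reproducibility:

* frequency: rare iff count < 4 (strict);
* expression: tertiles of the defined per-motif values (type-7 quantiles),
  low/medium/high; percentile ranks (`rank/n`, average ties) for the
  continuous view;
* cleavage: *low* iff score strictly below the first quartile (type-7);
* np-TCEM (a motif not expected to mediate positive selection): rare
  frequency OR expression below the bottom-tertile boundary OR
  thymoproteasomal score below the first quartile. Motifs whose expression
  is undefined (no mapped encoding gene) are treated as low expression by
  default — they cannot mediate selection through expression — with an
  `"ignore"` switch.

The expression cutoffs used in the immunogenicity odds-ratio analyses are not
universal constants; tertile boundaries are the package default and are
exposed as configuration.

## Dataset curation

Assay-level records are curated into two non-overlapping benchmark datasets.
Records are kept only for linear 9/10-mers over the 20 standard letters,
from nonhuman sources, tested against 4-digit HLA class I alleles. An
allele–peptide pair is *nonimmunogenic* when all its T cell assays are
negative and *immunogenic* when positives outnumber negatives; everything
else, and any peptide labelled inconsistently across alleles, is excluded.
Dataset 1 requires the binding to be confirmed by prediction (affinity
< 500 nM or rank percentile < 2). Dataset 2 requires empirical verification
(≥ 2 binding and ≥ 2 T cell assays, strictly more than 60% of binding assays
positive) and removes redundant sequences with an iterative k-tuple filter:
while any pair sits below distance 0.5, the member of the closest pair with
the smallest mean distance to the rest is dropped (ties broken by removing
the lexicographically smallest sequence, which makes the procedure
deterministic). The k-tuple distance is
$d = 1 - \mathrm{shared}_k / (\min(L_a, L_b) - k + 1)$ with multiset-counted
shared k-words and the protein default $k = 1$, under which the 0.5
threshold corresponds exactly to a maximal 50% residue overlap. Secondary
HLA anchors are detected as peptide positions whose amino-acid entropy over
allele-bound peptides falls below 0.8 *nats* (natural logarithm; with ~2
effective residues a position is clearly anchoring). The log base is a
genuine ambiguity; a bits convention would rescale the threshold, and the
entropy column is returned so users can re-threshold.

## Similarity and cross-reactivity

Peptide similarity is BLOSUM62-based with symmetric geometric-mean
normalization, $s(a,b)/\sqrt{s(a,a)\,s(b,b)}$, which equals 1 exactly on
identical sequences (BLOSUM62 diagonal entries are maximal within their
rows, asserted in the tests) and matches the scale on which a
cross-reactivity cutoff of about 0.6 is meaningful. The normalization is an
assumption — min-denominator variants exist — and is isolated in a single
scorer used by both the 5-mer motif comparisons and the 9-mer best-hit
analysis.

The best human hit of a peptide is found by an exhaustive scan over all
equal-length ungapped proteome windows. This is deliberately *not* a
heuristic search: at desk scale exhaustive scanning is cheap, strictly more
sensitive than heuristic seeding, and serves as its own definition (the test
suite checks it against a naive double loop).

TCR cross-reactivity is estimated from single-position mutational scans of
an epitope: variants keeping at least 10% of the original TCR binding are
*binders* (at the boundary, 10% counts as binding; below it activation is
negligible), a ROC curve of motif similarity against that label is swept
over observed scores, and the optimal cutoff maximises
$Se - m(1 - Sp)$ with $m = \text{cost ratio} \times (1-\pi)/\pi$ at
prevalence $\pi$ (sample prevalence by default; with cost ratio 1 and
$\pi = 0.5$ this is Youden's J). The cutoff is always an observed score, and
ties resolve to the smallest maximiser. The group-1 × group-2 scan then
reports, per repertoire-depleted motif, the fraction of the
repertoire-covered motif set within the cutoff, streaming one motif at a
time so the full pair matrix is never materialized; the pair count is
reported exactly.

## The synthetic-data world

Every input the pipeline consumes has a generator with planted, recoverable
structure; generators are pure functions of their parameters and a seed and
emit ground truth next to the data.

* **Proteomes.** `sim_proteome()` draws i.i.d. residues (optionally with
  exact-count planted motifs); `sim_structured_proteome()` composes proteins
  from 9-residue blocks whose motifs come from a Zipf-weighted pool,
  emulating the long-tailed TCEM frequency distribution of real proteomes at
  desk scale (60 proteins x 360 residues by default, about 21,000 windows).
  What it does not emulate: homology structure, domain grammar, realistic
  amino-acid composition. Passing recovery tests therefore demonstrate the
  pipeline's correctness, not biological effect sizes.
* **Expression.** Negative-binomial counts (dispersion 0.2) with a planted
  housekeeping set at 10x expression; motifs exclusive to housekeeping genes
  land in the top expression tertile.
* **Cleavage tables.** The immunoproteasome table equals its background. The
  thymoproteasome table carries a hydrophobic deficit on the N-side flank,
  strongest at position −1 ($\theta$, default 0.2) and decaying as
  $\theta^{1/|i|}$ toward −5. The grading is a deliberate design choice: the
  per-site score is a median of ten values, so perturbing position −1 alone
  can never move it — a single-position deficit is invisible *by
  construction* to the very cascade it is meant to exercise. The graded
  flank keeps the biological reading (reduced chymotrypsin-like activity,
  concentrated at the scissile bond) while making the planted effect
  recoverable; at $\theta = 1$ both tables are exactly uniform.
* **Immunogenicity.** Peptides carry motifs sampled from the proteome
  profile; the latent immunogenicity probability is
  $\mathrm{logit}^{-1}(\beta_0 + \beta_f[\text{count} \ge 4] +
  \beta_m[\text{mid-tertile expression}] + \beta_c[\text{thymo} \ge Q_1])$,
  and assay records are drawn so the labelling rules recover the latent
  label. A toy anchor-position predictor supplies binding tables, so no
  external tool is needed.
* **TCR scans.** All 19 substitutions at each of the five TCEM positions;
  relative binding $\max(0, e^{\lambda(\text{sim}-1)} + \mathcal N(0,\sigma))$.
  At $\sigma = 0$ the 10%-binder cutoff inverts analytically to
  $\text{sim}^* = 1 + \ln(0.1)/\lambda$, which the recovered ROC cutoff must
  match within one observed-score step.
* **Repertoires.** 22–27 individuals with 6-allele genotypes; recognition of
  each presented peptide is Bernoulli with base rate 0.5, multiplied by the
  np penalty (0.5 planted, 1 for the null).
* **Pathogens.** Mixtures of foreign (random) and host-copied segments. A
  small synthetic reference proteome necessarily has a high intrinsic np
  rate — most of its motifs are singletons — so a nominal target like "30%
  np windows" is not reachable by mixing; instead the generator emits the
  construction-derived expected fraction (foreign-interior windows ≈ 1,
  copied windows at their source stretch's measured rate) and recovery is
  checked against that expectation, with segment-boundary windows (8 per
  junction) as the uncontrolled remainder.
* **Associations.** Six risk and seven protective allele groups whose member
  alleles have high/low presented-np fractions, and per-study odds ratios
  increasing in the group mean; the rank-percentile aggregation (groups in
  ≥ 75% of studies, average of within-study OR rank percentiles, extremes
  labelled) must recover the planted roles.

## Numerical conventions and degenerate inputs

* Quantiles are type-7 (linear interpolation) throughout; "low" groups use
  strict inequality at the boundary.
* Medians over even counts are midpoint means (R's default).
* Fisher's exact test is two-sided with the cross-product odds ratio
  reported; zero cells flag the estimate as degenerate rather than erroring.
* Rank tests switch from exact to tie-corrected normal approximation above
  n = 50 per group; identical paired vectors return p = 1 with a warning.
* Logistic fits abort with a diagnostic when separation is suspected
  (|coefficient| > 15 on the logit scale).
* Windows containing non-standard letters (X, U, B, Z, ...) are skipped and
  tallied, never silently dropped; proteins shorter than 9 contribute no
  windows; duplicated protein identifiers are an error, duplicated sequences
  under different identifiers are counted separately (reference proteomes
  contain near-duplicate isoforms, and collapsing them is not obviously
  right).
* Hydrophobicity uses the Kyte–Doolittle scale averaged over the five motif
  residues; the scale choice is configuration, not substance.

## Problem sizes

The bundled tests and the acceptance script use a 60 x 360-residue
structured proteome (~21,000 windows, ~16,000 distinct motifs), assay
datasets of 1,500–2,000 peptides, 100 odds-ratio replicates, 50 lowess and
repertoire replicates, 30 association replicates, and one full-size
cross-reactivity scan (43 x 323,470 motif pairs). These sizes were chosen so
that every stochastic recovery check has comfortable statistical power while
a full run stays in the minutes range on a single core.

## Known limitations

* The synthetic world contains no real sequences; agreement with the
  published effect sizes on IEDB/UniProt/GEO snapshots is out of scope here.
* The BLOSUM62 normalization and the entropy log base are declared
  assumptions (see above); both are isolated behind switches.
* The exhaustive best-hit scan is quadratic in total proteome length times
  query count; at full human-proteome scale users should expect minutes per
  thousand queries, and a heuristic pre-filter may be preferable upstream.
* The k-tuple redundancy filter is declared a re-implementation of the
  published iterative procedure, not a byte-identical reproduction of any
  particular alignment tool's distance.
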