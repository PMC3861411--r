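---
title: "Models and methods behind tfannotate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tfannotate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tfannotate)
```

This vignette is the package's own account of its science: the models the
four annotation steps rest on, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical conventions, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## 1. Homology features for TF identification and classification

### The model

Steps 1 and 2 treat TF identification as supervised classification of a
protein sequence represented by its homology relations to proteins of known
class. The query is locally aligned (Smith–Waterman, affine gaps) to every
record of a labeled database; raw scores are converted into bit scores

$$ b = \frac{\lambda S - \ln K}{\ln 2}, $$

and for each class the bit-score distribution of that class's hits is
condensed into five percentiles $(p_0, p_{25}, p_{50}, p_{75}, p_{100})$.
Concatenating class blocks gives a 10-dimensional vector for TF/non-TF and
a 25-dimensional vector for the five superclasses. The representation is
invariant to hit order, robust to database size, and delegates all
discrimination to an ordinary classifier.

Key parameters and defaults:

* **Substitution matrix and gaps** — BLOSUM62, gap open 11, extend 1 (a gap
  of length $g$ costs $11 + g$). These mirror the standard protein-BLAST
  scoring scheme and are configurable via `scoring_scheme()`.
* **Karlin–Altschul constants** — $\lambda = 0.267$, $K = 0.041$, the
  published gapped BLOSUM62/(11,1) values. Whether gapped or ungapped
  constants were intended is not derivable from the workflow description we
  follow, so both are plain fields of `scoring_scheme()`. Because the
  percentile features are monotone transforms of raw scores, classifier
  rankings are insensitive to this choice; absolute bit values are not.
* **Quantile rule** — linear interpolation between order statistics
  (`type = 7`). With small hit lists the quartiles depend on the rule, so
  it is fixed and tested rather than left to chance.
* **Empty class blocks** — a class with no hits contributes a zero block
  plus a `missing_classes` attribute. Only a query with *no hits at all*
  yields a no-prediction outcome; an absent class block alone does not.

The four comparison encodings (compressed PSSM profile, $k$-mer counts,
pseudo amino-acid composition, domain composition) are implemented behind
the same matrix-in/classifier-out surface. Their conventions: PSSM profiles
use a single alignment pass with +1 pseudocounts, log2-odds against the
Robinson–Robinson background, 20×20 compression by query residue, division
by sequence length and logistic squashing $g(x) = 1/(1+e^{-x})$ (the
squashing function is stated only abstractly in the source material for
this construction; the logistic is the conventional choice). Pseudo
amino-acid features use Chou's original property triple (hydrophobicity,
hydrophilicity, side-chain mass), standardized over the 20 residues, with
defaults $\lambda = 4$ tiers and weight $w = 0.05$; $k$-mers default to
$k = 2$ (400 dimensions, directly comparable to the PSSM vector length).

### Multiclass strategies

`one_vs_rest()` trains one scorer per superclass; scores feed ROC analysis
directly. `train_ecoc()` implements the exhaustive error-correcting output
code: for $k$ classes, $2^{k-1}-1$ binary classifiers whose predicted bit
string is decoded by minimum Hamming distance over the code rows, ties
sharing probability equally. Row and column order are pinned to the
published five-class table (first row all ones; the remaining rows
enumerate the binary expansion of the column index), giving 15 base
classifiers for five classes, 7 for four, and a minimum pairwise row
distance of 8. The all-zeros bit pattern is decoded like any other string —
the convention for that corner case is not specified anywhere, and treating
it uniformly avoids a special case.

### Evaluation

`nested_cv()` runs stratified 4×4 nested cross-validation: hyperparameters
are chosen on inner folds only, the winner is refit on the outer training
split and scored once on the outer test split. Feature construction can be
a *builder function* receiving only training-row indices — for homology
features this is essential, because the subject database and its labels
must exclude test rows to avoid leakage (the test suite checks the builder
contract directly). Fold ROC curves retain their score thresholds so they
can be threshold-averaged: at every pooled cutoff the per-fold operating
points are averaged (pooled-cutoff averaging was chosen over fixed-FPR
interpolation; with tied scores it is deterministic and reproduces each
input curve exactly when curves coincide). avgROC is the unweighted mean of
fold AUCs, and the multiclass avgROC the unweighted mean of one-vs-rest
AUCs.

## 2. DNA-binding-domain identification

Domain-scan output (InterProScan-style TSV with a pipe-separated GO
column) is filtered by GO subtree membership: a domain is a DNA-binding
domain if any of its GO terms lies in the subtree rooted at the
"DNA binding" molecular function (GO:0003677), taken as the transitive
closure over `is_a` edges. `part_of` edges are excluded by default —
common practice for molecular-function subtrees — but can be enabled.
GO:0003700 ("DNA-binding transcription factor activity") plays a different
role: it triggers removal in the *non-TF label post-filter*
(`label_postfilter()`), which discards candidate non-TFs that appear in TF
databases or carry that term. Both GO ids are arguments, not constants.
Overlapping DBD annotations on one protein are merged into maximal
intervals before motif inference, because the transfer machinery consumes
domain sequences and duplicated overlapping segments would double-weight
residues.

## 3. Smax log-odds motif similarity

### Hit model

A hit of motif $X$ (length $L$) is a window whose summed per-position
log2-odds score — motif probabilities with pseudocount 0.01, against an
iid background, defaults uniform — reaches a threshold $t_X$. The original
similarity measure's hit convention (balanced type-I/type-II cutoffs) is
not restated in the material this package follows, so the package uses an
explicit, exactly computable stand-in: $t_X$ is the smallest achievable
score whose exact background exceedance probability is at most
$\alpha_{\mathrm{hit}}$ (default 0.01); if even the maximum score is more
probable, the maximum is used. The full score distribution is computed
exactly by recursive convolution over positions (support aggregated onto a
$10^{-4}$ grid only beyond $2\times10^5$ points, which default motif
lengths never reach). $\alpha_X$ is the exact hit probability at $t_X$.

### Joint hits and the score

$\gamma_{X,Y}(k)$ is the probability that a random iid sequence carries a
hit of $X$ at position 0 and a hit of $Y$ at offset $k$ (windows
overlapping by at least one position). It is computed *exactly*: the
letters of the overlap are enumerated ($4^{\text{overlap}}$ cases,
vectorized), and given those letters the two residual score sums are
independent, so their exact tail probabilities multiply. Only when an
overlap exceeds 10 positions are the least-informative shared columns
treated as non-shared (an approximation documented here and never
triggered at the default lengths). Then

$$ s(k) = \log_2 \frac{\gamma_{X,Y}(k)}{\alpha_X\,\alpha_Y},\qquad
   S^{\max} = \max_{k,\ \text{orders},\ \text{orientations}} s(k), $$

where orientations pair each motif with its reverse complement. Under an
iid background, reverse-complementing *both* motifs mirrors the sequence,
so scanning $(X,Y)$ and $(X,\bar Y)$ over both offset signs covers all four
orientation pairs and both orders; symmetry and reverse-complement
invariance are tested properties, and $\gamma$ is tested equal to full
$4^L$ enumeration on small covering windows. The normalized similarity
$s_{\mathrm{norm}} = S^{\max}(X,Y)/\sqrt{S^{\max}(X,X)S^{\max}(Y,Y)}$ is 1
on the diagonal; $d = \min(1, \max(0, 1-s_{\mathrm{norm}}))$ is the motif
distance. Conventions fixed here because no source states them: log base
2 throughout; $\gamma = 0$ everywhere (or negative $S^{\max}$, possible for
anti-correlated motifs) maps to $s_{\mathrm{norm}} = 0$, distance 1.

## 4. Motif transfer

Four DBD pair features feed an $\varepsilon$-SVR (RBF kernel,
$\varepsilon = 0.01$, C and $\gamma$ tuned by an internal 3-fold CV over
a small grid; features standardized by the SVM machinery; predictions
clipped to $[0,1]$):

* global alignment identity;
* local alignment score, self-normalized
  ($S(a,b)/\sqrt{S(a,a)S(b,b)}$) — also the pair eligibility criterion
  (training pairs and transfer candidates require > 0.3);
* the $(k,m) = (3,1)$ mismatch kernel by explicit neighborhood counting;
* the local alignment kernel (sum over all local alignments of
  $e^{\beta\,\mathrm{score}}$, $\beta = 0.5$, computed in C++ with running
  rescaling), both kernels self-normalized.

Secondary-structure similarity features are not part of the feature set:
the package is sequence-only by design, and the feature-ablation protocol
(`features =` argument of the evaluation functions) exists precisely to
quantify what each sequence kernel contributes. Models are trained per
superclass when a superclass has at least 20 eligible pairs, with a pooled
model as fallback — at desk-scale training-set sizes the pooled model is
regularly the one consulted.

Best-match selection: dynamic mode sets the threshold to
$\min(0.95, \max_i \widehat{s}_i)$ provided the best candidate reaches
0.5 — the highest admissible threshold retaining at least one match —
otherwise the query gets an explicit no-prediction outcome (an outcome,
not an error). The prediction confidence is the mean predicted similarity
of the selected matches (the original tool reports *a* confidence without
defining it; the mean was chosen and documented). The outlier filter
removes, in a single pass, PFMs whose mean Smax distance to the other
selected matrices reaches $\tau = 1.5$ times the grand mean of those
values; it never empties the set. Merging builds a UPGMA guide tree on
pairwise Smax distances and, at each internal node, aligns the two child
profiles by ungapped sliding offset over both orientations, maximizing
summed per-column Pearson correlation (degenerate constant columns compare
equal only if numerically equal); aligned columns are averaged weighted by
the number of contributing source matrices, overhangs are kept, columns
re-normalized. Gapped profile alignment and other tree methods are out of
scope.

The transfer evaluation (`pfm_transfer_eval()`) is a 4-fold protocol
stratified by superclass: for each held-out TF and each best-match
threshold on the ten-point grid over $[0.5, 0.95]$ it records whether a
prediction was possible (transfer *rate*) and, when possible, the Smax
distance between merged prediction and annotated PFM (transfer *error*),
plus one dynamic-threshold row. Because selected sets only shrink as the
threshold rises, the rate is non-increasing by construction; the error
means at thresholds retaining only a handful of queries are noisy, which
is why trend assertions in the tests restrict to thresholds retaining at
least 10% of queries.

## 5. The synthetic-data generator

`gen_tf_family()` builds a TF family from a superclass-specific DBD
consensus (30-residue seeds with the flavor of real families: bZIP-like,
C2H2-like, homeodomain-like, p53-like, HMG-like): each member is random
flank + consensus mutated at a per-site divergence rate + random flank,
with flanks drawn from the Robinson–Robinson background so alignment score
distributions are realistic. Each family has a seed motif whose columns
place probability $(1+c)/(4+c)$ on the consensus base (concentration
$c = 20$); a member's PFM mixes the seed with per-column symmetric
Dirichlet noise, mixing weight $\min(1, 1.5\times\text{realized
divergence})$ — so PFM distance is a noisy, increasing function of DBD
divergence, exactly the structure the transfer SVR assumes.
`gen_proteome()` assembles labeled proteomes whose superclass mixture
follows the reference stratum counts
(`superclass_reference_counts()`), emits cross-referenced domain/GO tables
(against a bundled, deliberately reduced synthetic GO subtree), and plants
two kinds of adversarial records: *decoy* non-TFs carrying a mutated DBD
segment with a DNA-binding GO annotation (emulating the confusability of
C2H2-type domains that occur in DNA-binding non-TFs), and a small
*mislabeled* fraction annotated with GO:0003700 to exercise the label
post-filter.

What passing tests on this generator do and do not show: they demonstrate
that the implementation recovers planted structure — separable families
are classified nearly perfectly, identical-DBD twins transfer their PFM at
distance ≈ 0, transfer error and rate fall as the threshold rises. They do
not demonstrate real-data performance: real proteomes have domain
architectures, compositional biases, and motif families that no
Dirichlet-mixing model reproduces, and absolute avgROC or transfer-rate
values on curated TF collections are not reproducible from synthetic data.

## 6. Numerical choices and problem sizes

* Score-threshold comparisons use a $10^{-9}$ tolerance on `>=`, applied
  identically in the convolution machinery and in the enumeration oracles.
* Ties in best-alignment offsets during merging resolve to the first
  maximum in a fixed scan order (forward orientation before reverse,
  offsets ascending) — merging is deterministic.
* ECOC decoding, fold assignment and every stochastic learner are seeded
  explicitly; a pipeline run is a pure function of (inputs, seed).
* Evaluation problem sizes were chosen once as the smallest at which the
  phenomena of interest are identifiable, and are stated with every
  result: classification uses 60 TFs (12 per superclass) + 120 non-TFs at
  sequence length ≈ 60; transfer uses 20 families × 4 members, DBD length
  30, motif length 6, divergence 0.2.

## 7. Known limitations

* The hit-threshold convention is a documented stand-in for the original
  measure's unpublished cutoff rule; absolute $s_{\mathrm{norm}}$ values
  depend on $\alpha_{\mathrm{hit}}$, though the induced rankings are
  stable.
* Under the generator's noise conditions the held-out SVR rank correlation
  between predicted and realized similarity plateaus around the high
  0.6s: an oracle given the true latent mixing weights only reaches ≈ 0.8,
  so most of the residual is irreducible target noise, not model error.
* The homology scan is exact Smith–Waterman without heuristic seeding: it
  matches the scoring model of BLAST but not its speed; databases beyond a
  few thousand sequences call for substituting an external scan via
  `ingest_tabular_hits()`.
* E-values are never computed; all filtering is by bit score.
* PSSM profiles come from a single alignment pass, not iterated
  PSI-BLAST-style refinement; users with externally computed profiles can
  supply their own hits.
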