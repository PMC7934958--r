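---
title: "Modelling immune gene repertoire evolution across a social-insect phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling immune gene repertoire evolution across a social-insect phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunevol)
```

## The scientific problem

Comparative immunology asks how gene repertoires — here, the ~dozens of
canonical insect immune gene families (GNBPs, PGRPs, C-type lectins,
CLIP proteases, defensins, lysozymes, thioredoxin peroxidases, ...) —
change as lineages evolve new lifestyles. In cockroaches and termites the
transition of interest is from solitary living through subsociality to
advanced eusociality. Three methodological pieces are needed and this
package implements all three:

1. **Curation**: turning noisy per-transcript evidence from de novo
   transcriptome assemblies into a defensible families x species gene
   count matrix;
2. **Phylogenetic signal**: asking whether gene counts track the
   phylogeny (related species resembling each other more than chance);
3. **Gene family evolution**: fitting a birth–death model of gene gain
   and loss with clade-specific rates, and localizing significant
   expansions and contractions to branches.

## The curation cascade

De novo transcriptomes overcount genes: assemblers emit multiple isoforms
per locus, fragments, contaminants, and chimeric annotations. The cascade
is deliberately conservative; a gene is counted only when several
independent lines of evidence agree. Filters run in a fixed order, and
every transcript receives exactly one logged decision:

1. **Taxonomy** — only transcripts whose lineage label contains
   *Metazoa* are treated as host genes (contaminant reads from gut
   microbes, fungi and plants are common in whole-body libraries).
   Unassigned labels are kept by default: absence of evidence is not
   treated as evidence of contamination.
2. **Domain assignment** — the best per-domain profile hit (independent
   E-value ≤ 1e-5 by default) maps to one candidate family through the
   family definition table. The threshold is configuration, not dogma.
3. **Homology agreement** — the best hit against the curated immune
   reference set must carry the same family label; a transcript whose
   domain says C-type lectin but whose best homolog is a GNBP is exactly
   the kind of artefact the cascade exists to remove. No homology hit at
   all is a drop by default (agreement needs a comparison object),
   configurable.
4. **Annotation agreement** — an external annotation (e.g. an
   assembly-annotation best hit), when present, must not contradict the
   candidate family. Absence of annotation is not disagreement.
5. **Length** — predicted proteins under 100 amino acids are dropped,
   except in antimicrobial-peptide families (defensins, termicins,
   attacins, drosomycins, diptericins), whose mature peptides are
   legitimately short. The upstream ORF caller already floors predictions
   at 60 aa.
6. **Isoform collapse** — transcripts sharing an assembler component and
   gene index are isoforms of one gene; one representative (longest
   protein, ties by expression then name) is kept. Same component but
   different gene index = putative paralogs, counted separately. In
   genome mode (validating against annotated gene models) this step and
   the expression flag are skipped.
7. **Expression flag** — genes with fewer than five total counts are
   flagged for review rather than silently dropped (strict mode drops
   them).

Counts in the final matrix are distinct accepted *genes*, never isoforms.

## Phylogenetic signal battery

Five statistics are computed for the species totals, each family row and
each functional-class aggregate; constant traits are skipped with a
notice.

- **Abouheif's C_mean**: `sum_{i != j} w_ij z_i z_j / sum z_i^2` with
  row-normalized proximities `w_ij = 1 / prod(out-degrees of internal
  nodes on the i–j path)` — a topology-only autocorrelation.
- **Moran's I** with phylogenetic weights. The weighting scheme behind a
  phylogenetic Moran's I is a modelling choice; the default here is
  inverse patristic distance, row-normalized, and it is exposed as
  configuration rather than asserted.
- **Blomberg's K and K***: the observed-to-Brownian-expected ratio of
  mean squared errors. The two variants differ only in which mean
  centres the numerator sum of squares. The default K centres on the
  GLS phylogenetic mean — the original definition, the convention
  `phytools::phylosig` uses, and the one whose denominator correction
  term is actually its Brownian expectation, so it calibrates to K ≈ 1
  under Brownian motion (verified by simulation in the tests). The
  `star` variant centres on the raw mean; it runs systematically below
  1 under Brownian motion because the raw sum of squares has a
  different expectation than the correction assumes. Published values
  are not always explicit about which convention they used, so both are
  implemented and labelled.
- **Pagel's λ**: ML estimate of the off-diagonal multiplier of the
  shared-path covariance, searched on [0, 1] by a grid scan plus Brent
  refinement (tolerance 1e-8), mean and rate profiled analytically;
  tested by likelihood ratio against λ = 0 on a χ²(1) reference.

Permutation tests use `p = (b + 1) / (n + 1)` (999 permutations by
default) so p-values never reach zero, and all seeds are explicit
arguments. Counts are treated as continuous traits by default; a
`log1p` option exists for heavy-tailed families.

## Birth–death model of family size evolution

A family of size *i* gains or loses one member at rate *i*λ each
(birth = death — the single-parameter model that the standard
gene-family tools fit by default; unequal birth/death is out of scope).
The branch transition law has a closed form in
`alpha = lambda * t / (1 + lambda * t)`:

```
P(c | s) = sum_{j=0}^{min(s,c)} C(s,j) C(s+c-j-1, s-1)
           alpha^(s+c-2j) (1-2*alpha)^j,     state 0 absorbing.
```

**A numerical note that matters.** The alternating sum above loses all
precision once `alpha > 1/2` (`lambda * t > 1`) — binomial-sized terms
cancel catastrophically and "probabilities" above 1 emerge, which would
silently corrupt any likelihood search whose box reaches large rates.
Because the linear birth–death process is a branching process, the
transition row for a parent of size *s* is equally the *s*-fold
convolution of the single-gene offspring law
`P(0) = alpha, P(k) = (1-alpha)^2 alpha^(k-1)`; that construction is
all-positive and stable everywhere, and it is what
`bd_transition_matrix()` uses (the closed form is kept for the scalar
API where it is stable). Both routes are verified against a matrix
exponential of the truncated generator to 1e-8.

Likelihoods use Felsenstein pruning on the truncated state space
`{0, ..., max_count}` with `max_count = 2 * max(observed) + 10` by
default (a count above the bound is an error, never a silent clamp;
enlarging the bound further changes log-likelihoods by < 1e-6). The root
prior is uniform on `{1, ..., max(observed) + 5}`: a family present in
the data is assumed present at the root, and the tools this emulates do
not print their internal choice, so it is declared configuration.
Clade-specific rates attach to branches through the tree's rate classes
(e.g. solitary vs social); backbone branches whose descendants span
classes must be labelled explicitly — there is no neutral default for an
ancestral state. Rate estimation maximizes the summed family
log-likelihoods on the log-rate scale (Brent for one rate; Nelder–Mead
with five deterministic starts for more; box `[1e-8, 10]` events per
gene per unit time).

**Family-wide p-values** follow the Monte Carlo logic of the standard
tools: the statistic is the family's log-likelihood under the fitted
model (lower = more surprising), referenced against families simulated
from that same model; since this null does not depend on the family, one
simulated set is shared across families in a run. **Ancestral sizes**
are the jointly most probable assignment (max-product dynamic
programming, ties toward the smaller size). **Branch p-values** are the
package's declared operationalization of branch-level testing: on each
branch the reconstructed parent-to-child transition probability is
compared to transition probabilities of descendants drawn from the
transition law *conditioned on the reconstructed parent size*. The
unconditioned alternative (marginalizing parents over the root prior)
was rejected because it makes the p-value track family size rather than
surprise: a large family's transitions are always less probable than a
small family's, so an unchanged branch of a big family would look
"significant". Conditioning restores the intended behaviour — an
unchanged branch under small rates gets p ≈ 1. Reporting uses the
two-level convention: a family-wide gate (default 0.05), then one star
at 0.05 and two at 0.01 on branches, with direction the sign of the
reconstructed size change.

## The synthetic-data module

Every pipeline input can be generated with known ground truth:

- `simulate_family_counts()` evolves counts under the birth–death model
  (exact inverse-CDF sampling of the branch transition law by default;
  an event-driven Gillespie sampler is kept as an independent
  cross-check — the two agree in distribution in the tests, and the
  exact sampler matches the analytic law by χ² goodness of fit).
- `simulate_bm_trait()` draws traits from `N(0, sigma2 * V_lambda)` for
  signal-statistic calibration and recovery tests. λ-recovery
  simulations run on `replicated_cherry_tree()` — many two-species
  clades with deep shared stems — because λ rescales off-diagonal
  covariance and its information content comes from replicated clades
  with strong shared paths. On coalescent-like shapes the λ profile
  likelihood is nearly flat between 0.3 and 0.7 (we verified that the
  replicate-averaged profile still peaks at the truth), so the per-
  replicate MLE scatters to the boundaries and its mean is biased at
  interior truths for any implementation; the cherry design is the
  shape on which mean-recovery statements about the estimator are
  meaningful.
- `generate_transcriptome_fixture()` writes complete per-species
  evidence bundles whose truth table plants, per species, clean
  multi-isoform genes, paralog pairs sharing an assembly component, and
  one decoy per filter (fragment, short AMP that must survive,
  family-disagreement, annotation-mismatch, low-expression,
  contaminant, missing/weak domain, missing homology). Residues are
  poly-alanine with length control — only lengths, headers and hit
  tables carry signal, which is exactly what the cascade consumes.

The bundled `fixture_tree()` is a *synthetic* 18-species
cockroach/termite phylogeny (2 solitary cockroaches, 2 subsocial wood
roaches, 8 lower and 6 higher termites; root at 150 My) with invented
but plausible divergence times; it is a test harness, not an estimate.
The default simulation truths are per-class rates of 0.0037 (solitary)
vs 0.0016 (social) events·gene⁻¹·My⁻¹, mirroring the published contrast
for this clade, with root sizes uniform on 1–10. The positive-control
fixture adds 6 families (on top of 60 background ones) whose within-clade
rate in the higher-termite clade is elevated to 0.02 — an order of
magnitude above background, the regime reported for episodically
expanding immune families; these settings were fixed a priori as the
simulation conditions.

What the fixtures deliberately do **not** emulate: realistic residues,
read-level noise, assembly chimerism, or correlated evolution between
families. Passing tests therefore demonstrate correctness of the
algorithms under their stated models, not robustness to every artefact
of real transcriptomes.

## Numerical choices and edge cases

- Ultrametricity is checked to a relative tolerance of 1e-6 (serialized
  trees lose precision); the check can be disabled for non-clock trees.
- Zero-variance traits are errors for every signal statistic
  ("degenerate trait"), and constant matrix rows are skipped, logged, in
  the battery.
- Permutation p-values use `(b + 1)/(n + 1)`; Monte Carlo p-values the
  same convention, so all p ∈ (0, 1].
- Isoform tie-breaks (longest protein, then counts, then name) and the
  domain-hit tie-break (best i-E-value, then score, then name) are
  total orders, making the cascade deterministic and idempotent.
- All simulations accept explicit integer seeds; fixed seed implies
  byte-identical fixture files and pipeline outputs.

## Problem sizes used in the validation suite

The test suite validates at sizes chosen to exercise every code path
while remaining routine on a laptop: exhaustive likelihood enumeration
on 5–6 tips with family sizes ≤ 5; rate recovery from 200–500 simulated
families on the 18-tip fixture tree (50 replicates for the two-class
ordering); p-value calibration from 1000 null families at 200
simulations each; signal calibration at 20–50 tips with 100–500
replicates; and 20 seeded end-to-end positive-control runs. These sizes
are statements about statistical sufficiency (binomial/KS error at the
asserted tolerances), not about the package's capacity.

## Known limitations

- Birth = death only; no gamma rate variation across families; no
  error model on tip counts.
- The λ search is confined to [0, 1]; trees whose structure supports
  λ > 1 are truncated to the boundary. On tree shapes with weak λ
  information the MLE piles up at 0 and 1 (a property of the
  likelihood, not the optimizer).
- Branch p-values condition on a point reconstruction of ancestral
  sizes and ignore reconstruction uncertainty.
- The curation cascade trusts its inputs' formats; it validates
  structure, not biology (e.g. it cannot detect a wrong taxon label).
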