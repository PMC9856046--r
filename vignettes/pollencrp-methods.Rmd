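---
title: "Models and methods behind pollencrp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pollencrp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `pollencrp`, the defaults
and the reasoning behind them, what the synthetic generators do and do not
emulate, and the numerical choices that matter for reproducibility.

# Cysteine-spacing grammars

Small cysteine-rich proteins (CRPs) are classified by the ordered spacing
of their conserved cysteines, not by overall sequence similarity. A family
pattern such as `CXXXXCX(7-8)CXCCX(6-8)CX(6)CXXXC` (the PCP-B family)
prescribes eight conserved cysteines with spacer-length ranges between
them. The parser reads each literal run of `k` X's as an exact spacer
`(k,k)`, `X(a)` as `(a,a)`, `X(a-b)` as `(a,b)`, and adjacent `CC` as a
zero-length spacer.

Three design choices are deliberate:

* **`X` excludes cysteine.** A match anchors on *consecutive* cysteines of
  the sequence's cysteine skeleton, so spacers are cysteine-free by
  construction. Allowing cysteines inside spacers would let any
  cysteine-dense sequence satisfy nearly any pattern, collapsing the
  family distinctions that the grammar exists to draw.
* **Typo normalization.** One shipped pattern row ends `...CXC(1-8)C`. A
  bracket can only quantify a spacer, never a cysteine, so `C(1-8)C` is
  read as `CX(1-8)C`, restoring the eight cysteines shared by the other
  rows of the family. The parsed object records that the normalization
  fired.
* **Position-free matching.** Nothing in the input marks where a mature
  peptide starts, so a match may begin at any cysteine, and cysteines
  outside the matched span do not invalidate a match (the larger nsLTP
  proteins carry the core skeleton inside a longer chain).

Classification applies a size filter first (default: at most 300 residues;
the shipped families span 52–265) and then matches each family's
*envelope* — the per-spacer interval hull of the per-species patterns — so
a protein from any of the three source species is accepted. Ties between
families are resolved deterministically: more matched cysteines win (the
12-cysteine GASA pattern beats any 8-cysteine family), then the more
specific pattern (smaller total spacer-range width), then a fixed family
order. The tie rule matters rarely; it exists so that results are
reproducible rather than order-dependent.

# Codon site models and the positive-selection scan

The selection module implements the Goldman–Yang codon substitution model
over the 61 sense codons of the standard genetic code. The instantaneous
rate from codon *i* to *j* is zero unless the codons differ at one
nucleotide position, and otherwise proportional to the target codon
frequency π<sub>j</sub>, multiplied by κ for transitions and ω = dN/dS for
nonsynonymous changes. Matrices are rescaled so one unit of branch length
is one expected substitution per codon; for site-class mixtures all class
matrices share the mixture-averaged scaling, which keeps branch lengths
interpretable across models.

Site-class models: M0 (one ω), M1a/M2a (nearly neutral vs positive
selection), M7 (ω ~ Beta(p,q) discretized into 10 equal-probability
categories represented by their conditional means) and M8 (the beta with
proportion p₀ plus a free class at ω_s ≥ 1). Ten categories follow the
standard convention for the beta models; the representative-value rule
(category means rather than medians) was chosen because the mean preserves
the class's expected rate.

Likelihoods are computed by Felsenstein pruning in a compiled
RcppArmadillo kernel. Each reversible class matrix is symmetrized with
√π, exponentiated through a symmetric eigendecomposition, and the per-site
class likelihoods are mixed with the class weights. Gaps, ambiguous codons
and (optionally) masked stop codons are marginalized as missing data at
the leaf. Per-site likelihoods on desk-scale trees stay far above the
double-precision underflow threshold, so no per-node rescaling is applied;
this is a known limitation for trees with hundreds of taxa, which are
outside this package's scope.

## Fitting

`fit_model()` maximizes the log-likelihood with a bounded quasi-Newton
optimizer (`nlminb`), with up to `n_starts` starts (one default start plus
random restarts drawn from a seeded private stream; default 3). Branch
lengths are estimated under M0 and then held fixed for the site-class
models — the common practical compromise that makes the four-model scan
affordable; per-model re-optimization is available by passing a tree with
the desired lengths and `branch_lengths = "fixed"`. κ is estimated in each
model unless fixed in the configuration. Codon frequencies default to
F3x4 (per-position nucleotide frequencies), with equal and F61 options;
the synthetic benchmarks use `"equal"` because the simulator draws from
uniform codon frequencies. Degenerate inputs are flagged rather than
fitted: an alignment without variable sites leaves ω unidentifiable, and a
fit that the optimizer does not report as converged carries a flag that
downstream posterior computations refuse.

The likelihood ratio test compares nested pairs (M7 vs M8, M1a vs M2a,
df = 2 — the number of extra free parameters), clamping the statistic at
zero when the alternative's optimum is numerically below the null's.
Significance stars follow the convention `*` p < 0.05, `**` p < 0.001,
`***` p < 0.0001. Under the null the statistic's true distribution is a
boundary mixture, so the χ²(2) reference is conservative; the test suite
verifies that the empirical rejection rate at 5% stays at or below 10%
over 100 null simulations.

## Bayes empirical Bayes sites

`beb_posteriors()` integrates the per-site posterior probability of the
ω_s class over parameter uncertainty: a uniform prior on a fixed grid of
(p, q, p₀, ω_s), 10 points per dimension, with grid points weighted by the
data likelihood. The priors are uniform on (0, 4) for p and q (covering
the shapes seen in practice for purifying-selection betas), (0, 1) for p₀
and (1, 11) for ω_s. Site likelihoods are tabulated once on a fine ω grid
(101 points on (0,1) plus the ω_s grid) with branch lengths, κ and the
rate scaling held at their maximum-likelihood values — the standard device
that makes the grid integration tractable, since each grid point then only
recombines class weights. Beta category means are mapped to the nearest
tabulated ω. The naive empirical Bayes variant (`neb_posteriors()`,
posteriors at the MLE without integration) is provided for comparison and
for models other than M8.

`flag_sites()` reports the 0.95 and 0.99 posterior tiers keyed to a
reference taxon's residues and marks cysteine columns, so the expectation
that conserved cysteines show no positive selection can be inspected
directly (it is a biological expectation, not an enforced constraint).

# Proteomic post-processing

Target–decoy FDR at threshold *s* is the decoy/target count ratio among
PSMs scoring at least *s*; the q-value of a PSM is the minimum FDR over
all thresholds that would accept it (computed by an exact sweep over the
observed scores), which makes q-values monotone in score. Decoys tied
with a threshold count against it — the conservative reading of ties. The
tier boundaries are 1% and 5%; the source text states both boundaries as
strict inequalities, so the 1% point itself is counted as high confidence
(logged choice). A +1 pseudocount on the decoy count is available but off
by default. Replicate merging uses union semantics with per-protein
replicate counts and relative abundance as percent of total peptide area.

# Enrichment statistics

Per term, the one-sided over-representation p-value is the hypergeometric
tail P(X ≥ k) with the term's background count K, background size N and
sample size n; fold enrichment is (k/n)/(K/N). "FDR correction" is
Benjamini–Hochberg over the tested terms — the standard meaning in the
classification systems this emulates. The reporting filter keeps terms
with fold strictly above 3 and p strictly below 0.05. Terms are flat
labels; ontology-graph propagation is out of scope.

# Expression specificity

Counts are normalized by median-of-ratios: each sample's size factor is
the median, over genes with nonzero counts in every sample, of the ratio
of the count to the gene's geometric mean. When no such gene exists the
strict method refuses, and a pseudo-reference fallback (geometric means
over nonzero entries) is available. "Specifically expressed in mature
anthers" is quantified as: peak target-tissue signal at or above an
expressed floor (default 10 normalized counts) with every reference
tissue below max(5% of the peak, 5 normalized counts). The source
material gives no numbers for "very little to no expression", so these
defaults were chosen once as a practical reading of that phrase and are
configurable; categorization is invariant to global rescaling when the
thresholds are scaled accordingly.

# Synthetic generators

The generators provide ground-truth-labelled inputs with the statistical
structure the analyses assume — no more:

* Protein sequences are drawn directly from the family grammars with a
  hydrophobic N-terminal prefix; they do not emulate real amino-acid
  composition, signal-peptide cleavage or homology between families.
* Codon alignments evolve gap-free along a given tree under the same
  model family the fits assume (M7/M8 data draw ω from the continuous
  beta, not the 10-category discretization used in fitting); there is no
  alignment error, indel process or among-site rate variation beyond ω.
* PSM scores are Gaussian mixtures with decoys drawn from the
  incorrect-match component, the property the target-decoy estimator
  relies on; they do not model score distributions of real search
  engines.
* Counts are negative binomial with configurable dispersion and
  deliberately unequal sequencing depths; planted specific genes have
  configurable reference-tissue leakage.

Passing tests on these inputs demonstrates internal correctness and
statistical calibration of the methods, not robustness to the
misspecifications of real data (alignment error, composition bias,
protein inference ambiguity).

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use desk-scale sizes chosen to
exercise the asymptotics without waste: quartets for the enumeration
oracle; 6 taxa × 60 codons for the 100-replicate null calibration (with a
single optimizer start — under-optimizing M8 only makes the test more
conservative); 8 taxa × 200–300 codons for parameter recovery and BEB
precision; 200–500 sequences per family for the grammar round trip. Every
stochastic step takes an explicit integer seed, generators call
`set.seed()` on entry, and the optimizer's restart draws come from a
private RNG stream, so a fixed seed reproduces every result bit for bit.
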