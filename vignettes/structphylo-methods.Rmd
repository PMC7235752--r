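---
title: "Models and methods in structphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in structphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`structphylo` tests whether protein sites in different structural
environments — solvent-exposed versus buried, and the three secondary
structure classes — carry different phylogenetic signals. This vignette
explains the models behind each stage, the parameters that matter, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the package's known limitations.

## Structural partitioning

Solvent accessibility and secondary structure are assigned once per
protein, not once per sequence, because protein structure diverges far
more slowly than sequence. Each gene alignment is reduced to a single
consensus sequence using Henikoff position-based weights: in a column
with $r$ distinct residue types in which residue $a$ occurs $n_a$
times, a sequence holding $a$ receives $1/(r\,n_a)$; weights are summed
over columns where the sequence is non-missing and normalized to sum 1.
The weighting damps the influence of densely sampled clades on the
consensus. The consensus residue of a column is the weight-sum argmax
over residues; ties are broken by the canonical residue order
(ARNDCQEGHILKMFPSTWYV) so the result is deterministic, and all-missing
columns become `X`. Normalizing the weights before scoring does not
change the argmax, so the choice is inert for the consensus; the
normalized weights are what the package reports.

Structure annotations (helix/sheet/coil and exposed/buried, the binary
call of accessibility predictors at a 25% relative-accessibility
threshold) are supplied per gene in predictor-output style and
extrapolated from the consensus to every taxon in the column. The
predictors themselves are external: the package consumes their output,
it does not reimplement them. Per-class extraction concatenates
matching columns in gene order and records each gene's contributed
interval as a CHARSET; columns that are entirely missing belong to no
class, since a structure predictor has nothing to annotate there. The
six combined classes therefore partition the annotated columns exactly
— a property the test suite asserts.

## The likelihood engine

All likelihood machinery is one generic $n$-state time-reversible
engine, instantiated at 20 (amino acids), 6 (Dayhoff-recoded) and 2
(RY-recoded) states. A model is a pair of exchangeabilities $r_{ij}$
and equilibrium frequencies $\pi$, giving $q_{ij} = r_{ij}\pi_j$ with
rows summing to zero and the whole matrix normalized so
$-\sum_i \pi_i q_{ii} = 1$; branch lengths are then expected
substitutions per site. Transition probabilities come from the
symmetric eigendecomposition of
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$, which is exact
and stable for reversible models and is cached per matrix.

Rate variation across sites uses the discrete-Gamma approximation with
equal-probability bins and *mean-of-bin* rates renormalized to mean 1
(the dominant convention among fast ML programs; the alternative
median-of-bin rule gives slightly different category rates). The
default is four categories; `p_inv` mixes in an invariant-site class in
the standard proportional way. Gap, `?`, `X` and the ambiguity codes
are all treated as missing data — all-ones partial likelihoods — but
preserved distinctly when files are written.

Felsenstein pruning rescales partial likelihoods at every internal
node, accumulating per-site log scale factors; without this, 19-taxon
deep-divergence problems underflow at a few hundred sites. Mixture
likelihoods (Gamma categories, profile components, the invariant class)
are combined per site by log-sum-exp.

### Fitting on a fixed topology

`fit_fixed_topology()` cycles over free-parameter blocks until the log
likelihood improves by less than `tol` (default $10^{-3}$):

* **Gamma shape and invariant proportion** — Brent (1-D) ascent, the
  shape on a log scale in $[0.02, 50]$, starting at 1.
* **Branch lengths** — per-branch Brent ascent on $[10^{-8}, 20]$ using
  up/down messages recomputed at the start of each sweep. Updates are
  only accepted when they improve the stale-message objective, and the
  outer loop re-evaluates the true likelihood, so the cycle terminates.
* **Exchangeabilities and frequencies** — an expectation-maximization
  scheme on expected sufficient statistics. For each edge (and each
  mixture component) the posterior joint distribution of the endpoint
  states is accumulated from the up/down messages; conditional expected
  substitution counts $N_{ij}$ and state waiting times $W_i$ follow in
  closed form from the eigendecomposition (the standard
  $\int_0^t e^{Qs} E_{ij} e^{Q(t-s)}\,ds$ integrals). The M-step then
  has a closed form for the exchangeabilities,
  $r_{ij} \propto (N_{ij}+N_{ji})/(W_i\pi_j + W_j\pi_i)$, and a
  one-dimensional fixed point for $\pi$. This is what makes the
  190-parameter amino-acid GTR fit practical: a naive coordinate ascent
  over 189 simplex coordinates needs thousands of full-likelihood
  evaluations per sweep, while one EM iteration costs about three. The
  E-step is validated in the tests against a discretized-integral
  oracle on small alphabets.

When the rate/frequency block is free, an overall rate scale is
implicitly free as well (the EM works with the unnormalized generator);
the returned model is renormalized to mean rate 1 and the returned
branch lengths absorb the scale, which leaves the likelihood unchanged.
The free-parameter census used for AICc counts $2N-3$ branch lengths,
1 for the shape, 1 for the invariant proportion, $A-1$ frequencies and
$A(A-1)/2 - 1$ exchangeabilities; at 19 taxa and 20 states this gives
$k = 55$ for an empirical-matrix fit with free frequencies and
$k = 244$ for the full GTR fit, the bookkeeping the AICc tests pin
down. AICc is the standard small-sample form
$2k - 2\ln L + (2k^2+2k)/(n-k-1)$ with $n$ the site count.

### Profile mixtures

CAT-type profile mixtures share one exchangeability matrix across many
frequency profiles; each profile's rate matrix is normalized
separately, and site likelihoods are weighted sums over profiles (and
Gamma categories) before logs are taken. Mixture weights are estimated
by exact EM on per-site per-profile likelihoods — monotone by
construction, which the tests assert on every run — and components
whose weights fall below $10^{-6}$ are flagged as zero-weight, a
pattern that large profile sets commonly produce. The optional FO
component's frequencies are estimated from the data: its update reuses
the expected-statistics machinery restricted to the component's
posterior weight, and is accepted only when it improves the likelihood,
so monotonicity survives. Profile width is summarized by the effective
alphabet size $\exp(-\sum_i \pi_i \ln \pi_i)$, the exponential Shannon
entropy: 20 for the uniform profile, 1 for a point mass, 18.04 for the
LG frequencies.

**The bundled profile sets are synthetic stand-ins.** The published
C-series profile constants are not redistributed here;
`synthetic_profiles(n)` builds deterministic sets (Dirichlet draws
centred on the LG frequencies with concentrations log-spaced from
narrow to wide, fixed internal seed) that emulate only the qualitative
narrow-to-wide spread. Analyses that need the published sets should
load them with `fit_profile_mixture(profiles = <matrix>)` after
obtaining them from their original distribution. Consequently the
acceptance checks that compare profile-width statistics against the
published sets' values fail against the stand-ins by design, and the
acceptance script reports the stand-in statistics it actually computes.

## Decisive sites and the class contingency test

For two fixed candidate topologies, the per-site difference
$\Delta_i = \ln L_i(T_a) - \ln L_i(T_b)$ has mean $\mu$ and population
standard deviation $\sigma$; a site is *decisive* when
$|\Delta_i - \mu| > m\sigma$ (default $m = 5$), and it favours the
topology given by the sign of $\Delta_i$. Deviation is measured from
the mean by default because that is how the rule is usually stated;
`center = "zero"` switches to a fixed threshold. Counting decisive
sites by class and favoured topology gives a 2x2 table tested with
Fisher's exact test; the pipeline's default is one-sided, which is the
reading under which the published class counts reach significance
(two-sided they sit just above 0.02).

A calibration study in the acceptance suite simulates both classes
under the *same* topology in the weak-root-signal regime (the focal
stem collapsed to near zero, so decisive sites split between the
topologies) and checks the rejection rate at $\alpha = 0.05$ over 200
replicates. Two findings shape the design. First, the regime matters:
with a well-resolved root virtually no decisive site favours the wrong
topology, one column of the table is empty and the exact test is
vacuous. Second, centring matters: with the adaptive mean-centred rule
the threshold is estimated from the same sites it classifies, which
stabilizes the split and makes the Fisher test markedly conservative,
while the zero-centred rule is calibrated at the nominal rate. The
suite therefore checks exact calibration under the zero-centred rule
and validity (no anti-conservatism) under the mean-centred default,
both computed from the same simulations. The calibration suite uses
$m = 1$ and 1,500 sites per replicate so that each table cell holds
tens of sites and discreteness is negligible; $m = 5$ remains the
analysis default.

The per-gene outlier scan sums $\Delta_i$ within genes and flags a gene
when its absolute sum exceeds three times the largest among the other
genes — the rule that isolates a single against-the-grain gene (for
example a hidden paralog) in a concatenation.

## Model space

Each fitted model is its 190-element exchangeability vector normalized
to sum 1 (so the comparison is scale-free), compared by Euclidean
distance and embedded in two dimensions by classical (Torgerson) MDS:
double-centre the squared distances, eigendecompose, scale the top
eigenvectors by root eigenvalues. Axis signs are fixed by making the
first nonzero coordinate positive. Dimensions with non-positive
eigenvalues are zeroed with a warning rather than silently dropped.

Whether two classes' fitted matrices differ *more than sampling
variance allows* is judged against a subsampling null: sites are
sampled without replacement (the natural reading of drawing sites from
a fixed dataset), the model is refitted, and the distance to the
grand-fit vector recorded across a size grid. The package's default
grid spans 500 to 55,000 sites geometrically, the span of class sizes
this kind of supermatrix produces; normalized vectors are used
throughout, including in the null, for consistency. Frequency shifts
$\Delta_i = \pi^{class}_i - \pi^{ref}_i$ are correlated against
property scales — the Grantham polarity scale ships with the package;
other 20-value scales load from two-column files — as a sanity check
that the structural assignment behaves as protein chemistry predicts
(polar residues enriched at exposed sites, and so on).

## Composition and recoding

GARP/FYMINK ratios (residues from GC-rich codons over residues from
AT-rich codons) are computed per taxon on parsimony-informative sites;
a taxon with no FYMINK residues gets a missing ratio rather than an
error. Back-translation maps each residue to its possible nucleotides
at codon positions 1-2 under the standard genetic code; a cell counts
on a composition axis only when all its possible nucleotides lie on one
side (leucine's C-or-T first position is determinate on the
purine-pyrimidine axis but not on strong-weak or amino-keto), and
informativeness of the expanded columns is judged over fully
determinate cells only, since the rule is not defined at the ambiguity
level.

Dayhoff six-state recoding collapses the alphabet into the six
physicochemical classes; RY recoding expands each residue into three
binary columns (purine 0, pyrimidine 1, mixed `?`) and drops columns
with no determinate cell, keeping a provenance map from output columns
to (input column, codon position). The ambiguity codes B and Z take
the positionwise intersection of their members' codes — a package
decision, since the rule is usually stated only for the twenty standard
residues. Recoded matrices feed straight back into the same likelihood
engine at 6 or 2 states.

## The synthetic-data generator

`simulate_alignment()` emulates the statistical shape of the target
data: ~19 taxa on the candidate-topology presets, many concatenated
genes, two interleaved site classes under distinct GTR+Gamma processes,
~20% missing data, and optional lineage-specific compositional drift
(the equilibrium frequencies are swapped and the generator renormalized
on chosen terminal branches — a minimal non-stationary mechanism in the
direction of GC-content drift). Default class models share LG
exchangeabilities but tilt frequencies toward polar residues for the
exposed class and hydrophobic residues for the buried class, with the
exposed class evolving 1.6x faster and with a slightly larger Gamma
shape — mirroring the empirical regularities that exposed sites are
more polar and faster-evolving. Default desk-scale size is 20 genes of
150 sites; the acceptance experiments state their own sizes (5,000
sites for parameter recovery, 3,000 for mixture-weight recovery, 1,500
per calibration replicate, 400 per power replicate).

What the generator does **not** emulate: structured missingness (real
supermatrices lose whole genes per taxon; masking is uniform at
random), indels and alignment error, predictor error in the structure
annotations (true class labels are returned), and gene-tree discordance
(all sites share one topology unless classes are simulated on different
trees on purpose). Tests that pass on this generator therefore validate
the estimators and bookkeeping, not robustness to those real-data
pathologies.

## Numerical choices and limitations

* Consensus ties: canonical residue order. MDS axis signs: first
  nonzero coordinate positive. Both purely for determinism.
* Population (not sample) SD in the decisive-site rule; immaterial at
  supermatrix scale, fixed for determinism.
* Retention-index characters with equal minimum and maximum steps
  (constant or nearly so) are excluded from both sums, the usual
  ensemble convention.
* EM stops on a likelihood gain below $10^{-3}$ or 500 iterations;
  weights below $10^{-6}$ are reported as zero-weight components.
* Optimization starts: shape 1.0, branch lengths 0.1 when absent,
  frequencies at observed counts (with a half-count pseudocount).
* Brent-based branch optimization uses messages that go stale within a
  sweep; it converges in practice but is not guaranteed monotone within
  a sweep, so the outer loop always re-scores the true likelihood.
* The engine targets fixed candidate topologies; there is no tree
  search, and Bayesian profile mixtures (Dirichlet-process profiles)
  are out of scope.
* Published AICc tables in this literature can be mutually inconsistent
  at the percent level in the implied site counts between rows; the
  package treats each row's implied $(k, n)$ on its own terms rather
  than resolving the inconsistency.
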