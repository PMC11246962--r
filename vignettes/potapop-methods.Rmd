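---
title: "Methods: genotyping QC, admixture and core selection for polyploid genebank collections"
author: "potapop maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping QC, admixture and core selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potapop)
```

# Scope and data model

`potapop` analyses SNP-array dosage genotypes of clonally maintained,
mixed-ploidy germplasm collections — the setting of large cultivated-potato
genebanks, where diploid, triploid, tetraploid and pentaploid landraces sit
in one collection and every accession exists both as a field-grown mother
plant and as *in vitro* plantlets. The pipeline covers: paired-sample
fingerprint identity QC; SNP-based ploidy prediction and heterozygosity;
Bayesian admixture with model selection over the number of ancestral
populations; a rule-based taxonomic classifier driven by admixture
proportions; UPGMA/PCA diversity analysis; and core / mini-core subset
selection.

## Call encodings

Arrays genotype every sample with a fixed cluster file, without knowing its
ploidy. Five-cluster calling resolves the tetraploid dosage classes
nulliplex (0) to quadruplex (4); three-cluster calling resolves diploid
AA/AB/BB as 0/1/2. A `genotype_matrix` therefore stores **class calls on
the encoding's own scale** (0..4 or 0..2) for every accession, with
per-accession biological ploidy carried as metadata. Under five-cluster
calling a diploid heterozygote is called duplex (class 2) and a triploid's
1/3 and 2/3 allele ratios land in the simplex and triplex classes — the
nearest class to the true allele ratio. This ploidy-agnostic observation
model is what makes SNP-based ploidy prediction possible at all, and it is
exactly what the simulator emulates: the observed class is
`round(scale * dosage / ploidy)`. True B-copy dosages are recovered for
model fitting with `as_dosage()` (`round(ploidy * class / scale)`).

Missing calls are the token `NA` in files and `NA` integers in memory,
never dosage 0. Filtering follows genebank QC convention: samples with
20% or more missing calls are removed, then markers without a clear
signal in at least 10% of the remaining individuals; both thresholds use
a closed (≥) comparison and are configurable.

# The synthetic collection generator

Every downstream stage is exercised on synthetic collections with full
ground truth (`sim_config()` / `simulate_collection()`). The generative
model is the standard independent-frequency admixture construction:

* per marker, a shared ancestral allele frequency $p \sim U(0.05, 0.95)$;
* population $k$ draws its frequency from the Balding–Nichols beta
  distribution $\mathrm{Beta}\!\big(p(1-F)/F,\,(1-p)(1-F)/F\big)$, with
  mean $p$ and variance $p(1-p)F$;
* accession $i$ draws admixture proportions
  $q_i \sim \mathrm{Dirichlet}(\alpha \mathbf 1_K)$ and a ploidy from the
  configured mix; each of its ploidy allele copies independently picks a
  source population from $q_i$ and is a B allele with that population's
  frequency;
* the B-copy count is reported as the nearest array class, miscalled to an
  adjacent class (reflected at the bounds) with the configured error rate,
  and masked at the missingness rate;
* every accession is duplicated as an *in vitro* partner with fresh noise;
  with the configured pair-error probability the partner instead carries
  the genotype of a different, randomly chosen accession, emulating
  decades of handling mistakes.

## Default conditions

The defaults describe a desk-scale collection with the character of a
large Andean potato genebank: ploidy mix 15.5% / 5.1% / 79.2% / 0.2%
(2x/3x/4x/5x, the proportions of a 3,860-accession collection), pair
error rate 19.9% (the rate such a collection's fingerprinting campaign
revealed), 2% missing calls, and 0.3% adjacent-class miscalls —
SNP-array replicate reproducibility is typically above 99%, and this rate
keeps same-clone pair concordance (~0.994) clearly separated from the
0.98 true-to-type threshold. Differentiation and admixture defaults
(`fst = 0.15`, `alpha = 0.2`) are field-plausible placeholders for Andean
potato lineages, exposed in the config; no published estimates pin them.
Generation uses independent frequencies across populations (no F-model
correlation) and unlinked loci; passing tests on these data therefore
says nothing about robustness to linkage or correlated drift on real
arrays.

Determinism: one master seed, with fixed offsets per stage
(frequencies +1, accessions +2, pairs +3); identical config and seed give
byte-identical outputs.

# Identity QC

Concordance between two call vectors is the fraction of identically
called markers among those called in both. A pair is true-to-type at
concordance ≥ 0.98 over ≥ 500 jointly called loci (defaults; the
pipeline scales the overlap requirement down for small marker panels).
No published numeric threshold exists for this decision — mismatched
pairs in practice are distinct genotypes far below any sensible cutoff —
so 0.98 is chosen to tolerate array-level miscalls while separating
distinct clones, and is exposed in the config together with the minimum
overlap. The collection error rate is
mismatches / (mismatches + true-to-type); pairs with insufficient data
leave the denominator. Duplicate detection single-links the graph of
pairs with concordance ≥ 0.995 — stricter than the true-to-type
threshold, because a duplicate group claims genetic identity rather than
clonal descent.

# Ploidy and heterozygosity

Heterozygosity is the percentage of called loci strictly between the
homozygous classes (0 and the encoding scale). On five-cluster calls this
is ploidy-agnostic; on true dosages the upper bound is the ploidy.

Ploidy prediction reads the five-cluster profile:

* duplex share of heterozygous calls ≥ 0.9 → diploid (AB has nowhere
  else to go);
* simplex+triplex share ≥ 0.9 → triploid (1/3 and 2/3 ratios);
* otherwise tetraploid versus pentaploid: call 5x when
  duplex share + heterozygous fraction ≥ 1.02 and all five classes are
  present.

The published source for this procedure states only that SNP data
predicted ploidy; the decision thresholds here are this package's own,
calibrated on the generator under its default noise. The 4x/5x statistic
was chosen because pentaploids fold B-copy counts 2 *and* 3 into the
duplex class and carry more heterozygous copies, so the *sum* of the two
fractions separates the profiles better than either alone (about 1%
error each way at 300 markers, several-fold better than the best
single-statistic rule we examined). The split remains the least certain call — real
pentaploids are rare — so the margin is reported as a confidence and the
thresholds sit in `ploidy_thresholds()`. Predictions need at least 50
heterozygous calls; accessions below that are reported as undetermined,
not guessed.

# Admixture

`fit_admixture()` implements the admixture model with independent allele
frequencies for arbitrary-ploidy dosage data. Population frequencies
carry a $\mathrm{Beta}(\lambda, \lambda)$ prior ($\lambda = 0.5433$ by
default, the value estimated for the potato collection that motivated
this package); accessions carry a fixed-$\alpha$ Dirichlet admixture
prior ($\alpha = 0.2$; a Metropolis update on $\alpha$ is a deliberate
non-feature to keep runs deterministic and cheap). An accession
contributes ploidy allele copies per locus; its dosage call is treated as
an exact B-copy count whose partition among populations is the latent
variable of a collapsed-free Gibbs sweep:

1. each B copy joins population $k$ with probability
   $\propto q_{ik} p_{kl}$, each A copy $\propto q_{ik}(1-p_{kl})$;
2. $p_{kl} \mid \cdot \sim \mathrm{Beta}(\lambda + n^B_{kl},
   \lambda + n^A_{kl})$;
3. $q_i \mid \cdot \sim \mathrm{Dirichlet}(\alpha + n_{i\cdot})$.

Under this model a dosage is marginally
$\mathrm{Binomial}(\text{ploidy}, \sum_k q_{ik} p_{kl})$, which is the
recorded log-likelihood $L(K)$. Missing calls contribute nothing. The
correlated-frequency F-model is out of scope; for strongly drifted,
recently diverged populations the independent-frequency model can need
larger $K$ to absorb correlation, which is one reason replicate sweeps
and ΔK — not a single fit — decide $K$.

Numerical choices: frequencies are clamped to $(10^{-9}, 1-10^{-9})$ and
Q entries to $\ge 10^{-12}$ before renormalisation; chains are
initialised from prior draws (P) and the uniform simplex (Q). Default
chain lengths are desk-scale (2,000 + 2,000 sweeps; production-fidelity
lengths such as 500,000 are accepted through the same arguments).
Convergence is flagged by comparing split-half posterior means of Q
(maximum entry difference ≤ 0.15).

The sampler's RNG is counter-based (splitmix64 streams keyed by hashed
accession and marker identifiers, the sweep index and a role tag), so
every draw is attached to content rather than to loop position:
permuting the input rows permutes the posterior-mean Q rows exactly, and
replicate runs differ only through their seeds.

Replicates and model selection: `run_k_sweep()` runs each $K$ in
replicate (three by default), aligns cluster labels (exhaustive best
permutation for $K \le 8$, greedy correlation matching above), averages
aligned replicates, and computes the Evanno statistic
$\Delta K = |L(K{+}1) - 2L(K) + L(K{-}1)| / \mathrm{sd}(L(K))$, defined
only for interior $K$ with positive replicate standard deviation; the
argmax is the selected $K$.

# Rule-based species prediction

The classifier applies per-species interval constraints on the six named
cluster frequencies (yellow, red, blue, pink, teal, green) from a CSV
rule table shipped as data (`inst/extdata/cluster_rules.csv`), so a
corrected transcription never touches code. Cells are empty
(unconstrained), `NO` (zero value), `-` (low to no value), `>x`, `<x` or
`a-b`, in percent.

The original procedure was manual colour-scale inspection in a
spreadsheet; a reproducible scoring policy has to be defined here, and
its free parameters were fixed by one requirement: the fourteen
published worked examples (shipped in
`inst/extdata/worked_examples_q.csv`) must classify exactly to their
printed species. The policy:

* constraint satisfaction is 1 inside the closed interval and within
  `tolerance` (5) percentage points of it, then decays linearly to 0
  over a further `tolerance`; zero-value cells get full credit only up
  to `epsilon` (0.5) and decay immediately beyond it, with no plateau;
  "low" cells are the interval [0, `low_cap` = 10];
* each constraint is weighted by its narrowness, $w = 1 -
  \text{width}/100$, so a satisfied 10–40% band says far more than a
  satisfied <60% bound; the species score is the weighted mean
  satisfaction;
* the primary call is the top score; exact ties go to the species with
  the narrower (more specific) mean constraint, then lexicographic; a
  runner-up within `hybrid_margin` (0.1) flags a putative hybrid with
  both species as parent candidates; an all-zero score is
  "unclassified".

The plateau and the narrowness weighting are load-bearing, not cosmetic.
One published accession (q = 0, 0.565, 0, 0, 0.434, 0) strictly
satisfies every constraint of the broad STN row while missing GON's
10–40% teal band by 3.4 points, yet its printed call is GON: only a
policy that forgives small boundary misses *and* privileges narrow,
informative constraints reproduces that call, and an unweighted
satisfied-fraction score provably cannot. Accuracy evaluation reports
primary and hybrid-extended percent correct (a call also counts when the
confirmed label equals a hybrid parent candidate); accessions without a
usable confirmed label (`SOL`/`ND`) leave the denominator.

With fewer than six fitted clusters the trailing named clusters are
padded with zero ancestry so exploratory runs still classify; a
six-cluster fit is the intended regime.

# Diversity

The distance metric behind the published trees is not recoverable from
the text, so both candidates are first-class: simple mismatch
(1 − concordance over jointly called loci; default, encoding-agnostic
across mixed ploidies) and Euclidean distance on scale-normalised calls.
UPGMA is implemented directly so its contract is pinned: size-weighted
average linkage, equal minimal distances broken toward the pair whose
smallest member ids sort first, node heights at half the joining
distance (hence ultrametric trees whose cophenetic distances reconstruct
joining distances; `stats::hclust`/`stats::cophenetic` serve as an
independent oracle in the tests, not as the implementation). Newick
export orders children canonically by smallest contained leaf id, so the
text is invariant to input row order. PCA scale-normalises calls,
mean-imputes missing values per marker, centres columns and delegates to
`stats::prcomp`, reporting percent variance per component.

# Core and mini-core selection

The selection objective is accession-to-nearest-entry (ANE): the mean,
over all accessions, of the distance to the closest selected entry. The
published workflow used an external optimiser with this objective and a
selection fraction of 11.68% (451 entries from 3,860 accessions); the
optimiser here is this package's own and deliberately simple — greedy
farthest-point seeding from each of five deterministic medoid-ranked
starts, steepest-descent single-swap local search, best start wins, all
ties broken lexicographically so the result is seedless and
relabelling-invariant. On toy instances (n = 12, k = 3) it matches
exhaustive search in ~98 of 100 cases (single-start landed at ~85,
which motivated the multi-start). The mini core re-runs the optimiser
with candidates restricted to core members while still evaluating the
objective over the whole collection, so mini entries represent
everything; by construction the mini core is nested and its objective is
never better than the core's. Curator-style manual substitutions are
supported only as a post-hoc list that the composition report
re-validates.

# Pipeline

`run_pipeline()` chains simulate/ingest → filter → identity → ploidy →
admixture → classify → diversity → core, one directory per stage, with a
manifest of every artifact and its MD5 checksum; identical config and
seed reproduce identical checksums. Unknown config keys are rejected
before any stage runs. Stage parameters above appear in the config with
the same defaults. Admixture inside the pipeline uses the predicted
ploidy (falling back to declared ploidy where prediction was
undetermined), mirroring the predict-first dependency order.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations run at desk scale,
chosen as the smallest sizes at which each property is comfortably
identified: Q recovery at 120 accessions × 300 markers (3 populations,
Fst 0.2, α 0.1; 2,000 + 2,000 sweeps; mean absolute error ≈ 0.036);
ΔK selection over K = 1–6 at 100 accessions × 250–500 markers with
triplicate chains of roughly a thousand sweeps each way (marker count
matters here: with few loci the realized population geometry can be
accidentally hierarchical, and ΔK then reports the top split — its
documented behaviour — rather than the true K); ploidy recovery at 150–200 accessions per ploidy class; pair
error recovery at 2,000 pairs × 300 markers; classifier accuracy at 150
accessions with an estimated six-cluster Q. Real-collection figures
(thousands of accessions, ~5,000 markers, 500,000-sweep chains) are
reachable through the same interfaces.

# Known limitations

* Independent-frequency model only; no F-model, no linkage model, no
  location priors.
* Dosage calls are taken as exact; there is no genotype-uncertainty
  layer between array intensities and calls.
* The 4x/5x ploidy split is heuristic and calibrated on the generator's
  noise model; flow-cytometry confirmation is out of scope.
* Cross-ploidy identity comparison assumes both members share a call
  encoding; within-tube mixtures of plantlets are not modelled.
* The classifier's defaults are fitted to fourteen worked examples; on
  collections whose cluster definitions differ, the rule table and
  policy parameters must be re-derived.
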