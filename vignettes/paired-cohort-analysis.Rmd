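---
title: "Statistical methods for partially paired low-biomass 16S cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for partially paired low-biomass 16S cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`paired16S` implements the downstream statistical analysis of a partially
paired tumor/noncancerous 16S rRNA tissue cohort: some patients contribute
both a lung adenocarcinoma (LUAD) and a distal noncancerous (NC) sample,
others only one. Every stage of the package respects that structure — mixed
models carry a patient random intercept, and every resampling procedure
resamples whole patients so that paired samples travel together.

The package starts from denoised feature tables (ASV counts, plus predicted
KO/pathway scores); read processing, denoising, taxonomy assignment and
contamination removal are upstream and out of scope.

# The paired design and the mixed model

All per-feature and per-index group comparisons use the Gaussian
random-intercept model

$$ y_{ps} = \beta_0 + \beta\,\mathbb{1}[\text{tissue}_{ps} = \text{LUAD}]
   + u_p + \varepsilon_{ps}, \qquad u_p \sim N(0, \sigma_u^2), $$

fitted by REML (`lme4`). The coefficient $\beta$ always reads LUAD minus NC.

**Inference.** The tissue coefficient is tested with a Wald *t* statistic on
Kenward-Roger denominator degrees of freedom (`pbkrtest` via `lmerTest`),
falling back to Satterthwaite and then to a large-sample *z* only when the
small-sample computations degenerate. This choice is empirical: on null
cohorts of ~30 patients with a partial pairing fraction around 0.4, the
large-sample *z* reference gives a type-I error near 0.09–0.12 and
Satterthwaite near 0.08–0.10, driven by the half of fits where a truly zero
patient variance is estimated as positive and distorts the partially paired
GLS contrast. Kenward-Roger brings the screen back to ~0.06, which the
package's own calibration tests verify. When the patient variance is
estimated on the boundary the fit coincides with OLS (flagged `boundary`);
degenerate responses (constants) return $\beta = 0$, $p = 1$.

Multiple testing is controlled with Benjamini-Hochberg throughout: across
genera for differential abundance (reported as *q* values), across indices
within a taxonomic level for alpha diversity, across pathways, and within
each direction separately for module scores.

# Compositional scale

Counts are analyzed on the centered log-ratio (CLR) scale:
$\mathrm{clr}_j(x) = \log(x_j + c) - \frac{1}{D}\sum_k \log(x_k + c)$.
Genus-level analyses use the pseudocount $c = 1$; continuous KO/pathway
scores are first renormalized per sample and use half the smallest nonzero
relative value (configurable). CLR with a fixed pseudocount is only
*approximately* invariant to per-sample library scaling; the identity
$\mathrm{clr}(\lambda x, \lambda c) = \mathrm{clr}(x, c)$ is exact and is
what the test suite asserts. A practical caveat verified during calibration:
in very narrow tables (ten-ish parts) every CLR column inherits a
non-negligible share of the noisiest column's heavy-tailed counting noise
through the geometric-mean term, which inflates the tails of downstream
tests. Real genus tables have hundreds of parts, where the effect is
negligible; simulated calibration cohorts therefore use realistic widths.

# Differential abundance

`differential_abundance()` applies a 15% prevalence filter (presence defined
as count > 0, pooled over both tissues), CLR-transforms with $c = 1$, and
runs the per-genus mixed-model screen with BH *q* values; genera with
*q* < 0.05 are labeled significant. This is a deliberate CLR + LMM analog of
a compound-Poisson (Tweedie) mixed model: it preserves the paired design and
the direction semantics of the coefficients while modeling log-ratio
abundances instead of raw counts. The substitution is recorded in every
pipeline run report.

# Diversity

Alpha diversity is computed on tables rarefied to the minimum sample depth
(single seeded draw without replacement; multi-draw averaging available).
Indices: observed richness, bias-corrected Chao1
$S + F_1(F_1-1)/(2(F_2+1))$, ACE with the standard rare-abundance cutoff of
10, Shannon entropy (natural log), and the Simpson dominance form
$\sum n_i(n_i-1)/(N(N-1))$ (1 = single-taxon community). ACE is undefined on
degenerate samples (e.g. all singletons) and reported `NA` there.

Beta diversity supports Bray-Curtis (on relative abundances), binary
Hamming (fraction of the table's features whose presence differs — literal
Hamming on fixed-length presence vectors; a pairwise-union denominator is
available), and unweighted/weighted (normalized) UniFrac via `phyloseq`.
PCoA uses Gower double-centering; negative eigenvalues are reported, not
corrected, and explained-variance fractions are taken over the positive
eigenvalues.

PERMANOVA uses Anderson's pseudo-*F* (via `vegan::adonis2` over an
explicitly generated, seeded permutation matrix) with unrestricted label
permutation and $p = (1 + \#\{F^\ast \ge F\})/(1 + B)$, $B = 999$ by
default. Unrestricted permutation treats samples as exchangeable; with
paired samples and a nonzero patient variance that assumption is violated,
so a restricted mode permuting within patients is available (`strata`), off
by default to match the unrestricted convention. The package's calibration
test therefore evaluates the unrestricted test on an exchangeable null.

# Marker stability selection

`stability_select()` runs a patient-level cluster bootstrap: each iteration
draws patients with replacement up to the original patient count; all
samples of a drawn patient enter training (duplicated per draw) and the
samples of undrawn patients form the out-of-bag (OOB) set. Per iteration,
features are CLR-transformed ($c = 1$) and Z-scored using training
statistics only; an elastic-net logistic model (mixing parameter 0.5 by
default) is fitted with the penalty chosen by patient-grouped
cross-validation over a 20-point logarithmic grid maximizing training-fold
AUC. Fold assignment shuffles patients within strata defined by their
tissue composition so folds cannot lose a class by construction. A feature
is "selected" when its coefficient is nonzero at the chosen penalty; the
stable panel is every feature whose selection frequency exceeds 0.60. Each
sample's OOB score is the mean (optionally median) predicted probability
over iterations where its patient was out of bag; `oob_roc()` summarizes
them with an AUC and a DeLong 95% CI (a patient-level bootstrap percentile
interval is available). `refit_panel()` reports apparent (training)
performance and log-odds coefficients from a lightly ridge-regularized
multivariable fit so the refit exists under complete separation (default
ridge penalty 0.01). Defaults the source protocol leaves unstated —
`n_bootstrap = 500`, the mixing parameter, the OOB aggregation rule, the CI
method — are package choices, all configurable.

# Co-occurrence networks

Within each tissue group, `build_network()` computes Spearman correlations
on within-group relative abundances (rank-based, hence invariant to
per-sample scaling) over genera passing a within-group prevalence filter
(default 0.2; a mean-abundance filter is available and off by default) and
keeps edges with $|\rho| \ge 0.7$ and two-sided $p < 0.05$ from the
*t*-approximation, without multiplicity correction — the conventional
thresholded construction. Topology: density $2E/(N(N-1))$, mean degree
$2E/N$, and the mean local clustering coefficient with nodes of degree < 2
contributing 0. Centralities: normalized degree, harmonic closeness
(finite on disconnected graphs), and normalized betweenness.
`bootstrap_stable_nodes()` repeats the construction over patient-level
bootstrap resamples, ranks nodes by the mean of their degree- and
closeness-centrality ranks (betweenness is reported separately as
"connector" evidence), and calls a node stable when it lands in the top 10
in at least 60% of iterations (all configurable; empty networks count as
iterations with no top nodes).

# KO screening with leave-one-patient-out stability

`ko_lopo_screen()` tests each KO's CLR abundance with the mixed model, then
refits once per patient with all of that patient's samples removed (LOPO).
Effects are summarized by the median LOPO estimate $\beta_{\mathrm{med}}$
and the sign consistency — the fraction of LOPO estimates sharing the sign
of $\beta_{\mathrm{med}}$ (defined 0 when $\beta_{\mathrm{med}} = 0$; the
reference sign could equally be taken from the full-data fit, which is left
as a documented alternative). Retention requires, conjunctively and with
inclusive boundaries, prevalence $\ge 0.20$, $|\beta_{\mathrm{med}}| \ge
0.30$ and consistency $\ge 0.90$; retained KOs are partitioned into LUAD-up
and LUAD-down subsets by the sign of $\beta_{\mathrm{med}}$. Module scores
are unweighted means of the subset's CLR values per sample (an
abundance-weighted variant is a natural extension), tested per
(module, direction) with BH within each direction. The biological KO-module
memberships used in tissue studies are curated from literature and are not
shipped; the module map is a required input, and the synthetic generator
emits an illustrative, non-biological map over ten named host-microbe
interaction modules.

# The synthetic cohort generator

The generator exists so that every stage is testable end to end without
external data; it is a first-class, tested module, not a fixture. It
emulates:

* **Design** — `n_patients = 34` each contributing a LUAD sample;
  a Bernoulli(14/34) subset adds an NC sample, matching a 34-tumor /
  ~17-NC / ~14-pair cohort in expectation.
* **Abundances** — a logistic-normal-multinomial model: genus log
  abundance = baseline (Normal(0, 1.5)) + patient intercept
  (SD `sigma_patient = 0.8`) + per-sample noise (SD 0.6) + a signed planted
  tissue effect for `n_planted_diff = 7` genera (|logFC| 1.5, alternating
  signs, drawn from the upper-baseline half so the effect is estimable on
  the CLR scale); softmax then a multinomial draw with log-normal library
  sizes (log-mean log(10⁴), log-SD 0.4, same order as real minimum depths).
* **Rare expansion** — 30 low-abundance taxa (baseline Normal(−3, 0.5))
  present with probability 0.05 in NC vs 0.25 in LUAD, so membership-based
  metrics separate the groups while abundance-weighted metrics barely move —
  the qualitative pattern tissue cohorts show.
* **ASVs and tree** — each genus splits into 1–6 ASVs with fixed Dirichlet
  weights (the genus table equals the aggregated ASV table exactly), and a
  random coalescent tree with exponential branch lengths covers the ASVs;
  the tree is deliberately free of biological claims.
* **Functions** — KO scores are a sparse nonnegative genus→KO loading (3
  source genera per KO, Gamma weights) applied to genus relative
  abundances with multiplicative log-normal noise (SD 0.3); 40 planted KOs
  are scaled by $e^{\pm 1}$ in LUAD; pathways are grouped sums; each KO
  belongs to exactly one module.

Because the patient intercept multiplies all genera equally, it cancels on
the CLR scale; patient-level dependence in the simulated compositions
enters only through the rare-expansion taxa and counting noise. The
generator therefore exercises the paired machinery structurally (resampling,
LOPO, grouped CV) more than it stresses variance partitioning. It also does
not simulate contamination, batch structure, phylogenetically clustered
effects, or correlated genus blocks (network tests construct latent-factor
blocks directly). Passing tests on synthetic cohorts show the procedures
are correct and calibrated under this model — not that the model captures
every property of real low-biomass tissue data.

Every bundle is byte-reproducible from `(config, seed)`;
`emit_fixture_bundle()` / `read_fixture_bundle()` round-trip the complete
bundle through plain-text formats (TSV, Newick, YAML).

# Numerical and degenerate-input choices

* Spearman *p* values use the *t*-approximation with average ranks
  (validated against exact permutation enumeration at small *n*); constant
  vectors yield `NA` with a warning.
* AUC follows the Mann-Whitney convention (ties count ½) with the ROC
  direction fixed (higher score = more LUAD-like), so null AUCs can fall
  below 0.5.
* Bootstrap resamples whose training set loses a class are redrawn (with a
  logged count); CV folds that still degenerate make the iteration report
  itself unusable rather than crash.
* Zero-variance features within a bootstrap training set are dropped from
  that iteration's standardization and get coefficient 0.
* Rarefaction below a sample's depth, trees missing table tips, KOs with
  two module assignments, unknown configuration keys, and negative or
  non-numeric table cells all fail fast with the offending item named.

# Pipeline reproducibility

`run_pipeline()` derives one seed per stage from the global seed, so runs
are reproducible stage by stage even when stages are skipped. All result
files are byte-identical across reruns with the same configuration and
seed; the run report (`run_report.yaml`) is deterministic and lists
versions, effective parameters, the seed and the documented methodological
substitutions, while wall-clock timings go to a separate `run_log.txt` that
is excluded from the determinism contract.

Test-suite and acceptance problem sizes (e.g. 50-replicate recovery runs at
60 patients, 200-replicate calibration runs at 30 patients, 100–200
bootstrap iterations) are the package's chosen desk-scale study conditions;
every threshold they exercise is the analysis default, not a value fitted
to the data.

# Known limitations

* The CLR + LMM differential-abundance engine is an analog of, not a
  reimplementation of, compound-Poisson count mixed models; zero-heavy,
  low-prevalence genera are handled through the prevalence filter rather
  than an explicit zero model.
* Unrestricted PERMANOVA on partially paired cohorts is anticonservative
  when the patient variance is large; use the restricted mode for strict
  type-I control.
* Co-occurrence edges are thresholded marginal rank correlations on
  compositional data; they describe co-variation, not ecological
  interaction, and no compositionality-aware inference (e.g. SparCC-style)
  is attempted.
* DeLong intervals treat samples as independent; with paired samples they
  are approximate, and the patient-level bootstrap interval is the
  conservative alternative.
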