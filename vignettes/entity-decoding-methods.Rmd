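---
title: "Decoding individual entities from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding individual entities from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(entityeeg)
```

# The scientific problem

How does the brain represent *individual entities* — specific people and
places known by a proper name — as opposed to the generic categories they
belong to? `entityeeg` implements a complete analysis pipeline for EEG
studies of this question, built around a hierarchical stimulus design:
2 coarse categories (people, places) x 4 fine-grained categories each x 4
individual entities per category, plus the 8 category nouns themselves —
40 stimuli in total. Two complementary analyses probe the structure of
the evoked responses:

1. **Time-resolved category classification.** A linear classifier is
   trained and tested separately at each timepoint of the evoked
   response, yielding an accuracy time course per subject; group-level
   significance uses threshold-free cluster enhancement (TFCE) with
   sign-flip permutations.
2. **Zero-shot decoding to entity vectors.** A ridge regression learns a
   linear map from whole-epoch features to distributional word vectors,
   evaluated with the leave-two-out pairwise protocol: the pair is
   decoded correctly when
   $\rho(e_1,\hat e_1)+\rho(e_2,\hat e_2) > \rho(e_1,\hat e_2)+\rho(e_2,\hat e_1)$,
   with $\rho$ the Spearman correlation. The held-out pair never
   contributes to training, so success requires genuine generalization
   to unseen entities.

Because no public recording of this kind is deposited, the package is
driven by a synthetic-data module whose generative model instantiates
exactly the assumptions the analyses test; real data can be supplied
through the documented epoch container and stimulus-table formats.

# The generative model

`generate_epoch_dataset()` simulates single trials as

$$x(s) = T_{\mathrm{coarse}(s)}\,\mathbf{1}_{[150,800]}
       + T_{\mathrm{fine}(s)}\,\mathbf{1}_{[300,450]}
       + (A\,v(s))\,\mathbf{1}_{[300,1100]} + \eta,$$

where the $T$'s are per-category channel templates, $A$ is a fixed
channels x dim forward map shared by a cohort, $v(s)$ is the stimulus's
entity vector, the indicators are boxcars over time windows in ms, and
$\eta$ is i.i.d. Gaussian sample noise. Entity vectors come from
`generate_entity_vectors()`:
$v(s) = \mu_{\mathrm{coarse}(s)} + \mu_{\mathrm{fine}(s)} + \varepsilon_s$,
a hierarchical model that reproduces the category-clustered geometry real
distributional vectors of people and places exhibit.

Key parameter choices, made once:

* **Geometry**: 128 channels at 256 Hz, epochs -100...1200 ms, 24
  repetitions per stimulus — the recording setup of the study design the
  pipeline targets.
* **Signal windows**: coarse 150-800 ms, fine 300-450 ms, entity
  300-1100 ms, matching where category- and identity-level information
  is typically reported in time-resolved EEG decoding.
* **Amplitudes vs noise**: template scales near 1 (coarse 1.0, fine 0.7,
  entity 0.5) against single-trial noise `noise_sd = 5`. Single-trial
  SNR is therefore low, as in raw EEG, while averaging 24 repetitions
  divides the noise variance by 24 and makes the planted effects
  recoverable — the regime the repetition count was chosen for.
* **Between-subject variability**: channel templates receive N(0, 0.2)
  jitter per subject; cohort-level objects (templates, $A$) are drawn
  once per cohort seed so subjects share signal structure.
* **Category nouns** share the category templates with entities by
  default (`noun_template_mixing = 1`); setting the mixing weight to 0
  gives nouns independent templates, the regime in which entity-to-noun
  transfer classification collapses to chance. Both regimes are needed
  to test the transfer analysis in both directions.

What the generator deliberately does **not** emulate: 1/f noise spectra,
volume conduction, artifacts, or any nonlinearity between vectors and
potentials. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the *analysis machinery* under the
linear-forward-model assumptions, not that real EEG satisfies those
assumptions.

# Preprocessing conventions

The canonical order is baseline correction (subtract the -100...0 ms
mean per trial and channel), repetition averaging (one evoked response
per stimulus), then channel standardization. Standardization pools all
stimuli and samples of a channel and uses the population (divide-by-N)
standard deviation; it is idempotent and invariant to channel-wise affine
maps. It is computed per subject on the averaged evoked set — the object
that enters classification and decoding. Whether the original analyses
standardized before or after averaging is not documented; this package
fixes the after-averaging convention and records it here rather than
presenting it as the original authors' choice.

**Sample-count convention.** Samples sit at $t_k = \mathrm{start} + k/f$
for $k = 0,\dots,\lfloor(\mathrm{end}-\mathrm{start})\,f\rfloor$ — 333
samples for -100...1200 ms at 256 Hz. A window $(a,b)$ covers sample
indices $\lfloor (a-t_0)f \rfloor$ through $\lfloor (b-t_0)f \rfloor$
(inclusive): a window edge falling between samples extends back to the
previous sample, so windows are never narrower than nominal. The
100-1200 ms decoding window thus covers 282 samples and the collapsed
feature vector has 128 x 282 = 36096 dimensions, flattened channel-major.

# Confound-controlled splits

Word length differs systematically between categories (people's full
names average 12 characters, place names 9), so a classifier could in
principle exploit orthographic rather than semantic signal. The package
enumerates *all* balanced held-out test sets (two people, two places, at
most one exemplar per fine category: 9216 candidates; or 96 within-coarse
leave-2-out pairs), encodes each test stimulus as its character length
and each label as the mean length of its entities, computes the Spearman
correlation $\rho$ between the two encodings, and retains the 50
candidates with the smallest $|\rho|$. Numerical choices: average ranks
for ties; $\rho \equiv 0$ when either encoding is constant (keeping
selection total on degenerate designs); ties in $|\rho|$ broken by the
deterministic lexicographic candidate order. The within-coarse
requirement that the two test stimuli come from different fine categories
extends the balance rule of the leave-4-out scheme to the leave-2-out
one.

# The classifier, and a calibration subtlety

The classifier is a linear max-margin model with C = 1.0 and l2
regularization; multiclass uses explicit one-vs-rest with
max-decision-value prediction. This package implements the
*squared-hinge* variant with the intercept included in the penalized
weights, solved exactly by a piecewise-Newton iteration in the span of
the training points (at most a few dozen samples, so each active-set
piece is a small linear solve).

The formulation matters more than is commonly appreciated. Under the
balanced split schemes, every held-out stimulus's class is the one with
the *fewest* remaining training exemplars (3 vs 4). On signal-free data
this depresses held-out accuracy below the nominal chance level: the
classic hinge-loss C-SVM with an unpenalized intercept measured at
roughly 10.4% against the 12.5% eight-class baseline and 16-20% against
the 25% within-coarse baseline, while the squared-hinge,
penalized-intercept formulation is far better calibrated (about 11% and
23% respectively). A residual deficit of one to two percentage points
remains for the multiclass tasks and is *structural*: it persists under
balanced class weighting and margin-normalized decision values, and is
intrinsic to held-out evaluation with under-represented test classes
rather than to any particular solver. The package's calibration tests
assert the baselines within 3.5 percentage points of nominal chance; the
residual bias should be kept in mind when interpreting accuracies very
close to chance.

# TFCE permutation inference

Group-level significance enhances the per-timepoint statistic (a
one-sample t across subjects by default; the plain mean by option) as

$$\mathrm{TFCE}(p) = \sum_{h = h_0 + dh,\, h_0+2dh,\dots}^{\,\le s(p)}
  e(h,p)^{E}\, h^{H}\, dh,$$

with $E = 0.5$, $H = 2$ (the conventional defaults of the widely used
implementations), a 50-step threshold grid up to the observed maximum,
and temporal adjacency of 10 ms — two samples belong to the same
suprathreshold run only if they are at most 10 ms apart, reflecting the
minimum duration of the post-synaptic potentials EEG measures. The null
distribution sign-flips whole subject rows and records the maximum
enhanced statistic (family-wise correction); the identity flip is always
included, so the smallest attainable p is $1/n_\mathrm{perm}$. Note the
enhanced statistic scales as $c^{H+1}$ when the statistic and $dh$ are
both scaled by $c$ — the $dh$ factor participates in the scaling.

# Zero-shot decoding choices

Ridge regression uses $\alpha = 1$ (the common library default) and is
computed in closed form through the kernel identity on centred data —
exact for any sample size and cheap when the feature dimension dwarfs
the number of stimuli. Exact ties in the pairwise inequality score 0.5,
the unbiased convention under symmetry. A leave-two-out subtlety worth
knowing: because the training mean excludes the held-out pair,
predictions are weakly *negatively* coupled to the held-out targets, so
the no-signal accuracy sits at or slightly below 0.5 rather than exactly
at it — the familiar cross-validation anti-correlation. The zero-shot
audit test exploits the sharp contrast between this regime (accuracy
well below 1) and what leakage would produce (an interpolating fit that
reproduces held-out vectors almost exactly, accuracy near 1).

The Wilcoxon signed-rank test (one-sample one-tailed for accuracies
against 0.5; paired two-sided for model comparisons) uses exact
enumeration for n <= 12 without ties and the tie-corrected normal
approximation otherwise; all-zero differences return p = 1 with a
warning, since such data carry no evidence against the null.
Benjamini-Hochberg FDR control is the standard step-up procedure.

# Entity-vector evaluation

Static entity vectors built from contextual language models are
aggregated mention-by-mention: up to the first 32 mentions, mean over
selected layers within a mention, then mean over mentions (the two means
commute). Vector quality is validated by Spearman correlation between
pairwise cosine similarities and human similarity/relatedness judgments,
and by K-means clustering scored with the adjusted Rand index under
coarse and fine labelings. K-means uses seeded random restarts (10 by
default, best within-cluster sum of squares kept) rather than a
spread-out initialization — with the well-separated category structure
at stake, restarts make initialization immaterial while keeping the
strict seed-determinism contract. The ARI convention for degenerate
cases: when both partitions are trivial (all singletons or a single
block) they are identical and the index is defined as 1. Running the
underlying language models is out of scope; mention vectors arrive from
files or from the synthetic generator, which makes the aggregation
protocol testable hermetically.

# Problem sizes used in the shipped analyses

The `analysis/` scripts simulate 10 subjects at a reduced geometry (32
channels, 128 Hz) and evaluate every 8th timepoint, which reproduces the
qualitative results of the full-size design in a few minutes on one CPU.
The test suite similarly uses 16-channel, 64 Hz subjects for pipeline
tests and the full 128-channel geometry where calibration itself is
under test. The acceptance script uses the full recording geometry with
one subject per baseline, 50 (or 96) splits and 20 evenly spaced
timepoints.

# Known limitations

* The synthetic generator's noise is white; no colored-noise or
  artifact model is provided.
* The session schedule's question randomization is a uniform shuffle of
  a fixed per-run question multiset; no constraint links questions to
  stimulus order.
* The held-out chance bias discussed above means baselines measured on
  finite designs sit one to two points below their nominal levels for
  multiclass tasks; studies comparing observed accuracies to nominal
  chance should prefer permutation nulls (as the TFCE machinery here
  does) over the theoretical constant.
* Spatio-temporal (channel-adjacency) TFCE and temporal-generalization
  analyses are out of scope.
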