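---
title: "Spectral sequence-activity modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral sequence-activity modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftsar)
```

## The problem

Directed evolution of an enzyme quickly runs into a combinatorial wall: once
a handful of beneficial point mutations is known, the number of their
combinations grows as $2^n$, while the wet-lab budget covers a dozen
constructs. The motivating case is the thermostability of the
(R)-selective &omega;-transaminase from *Aspergillus terreus* (325 residues):
six stabilizing substitutions (I77L, Q97E, H210N, N245D, G292D, I295V) span
a 64-variant library, of which 13 variants have measured half-lives
($T_{1/2}$ at 40&nbsp;&deg;C, the time for residual activity to drop to 50%).
The goal is a model, trained on those 13 sequences and activities alone, that
ranks all 64 variants and nominates combinations likely to beat the best
measured one.

`ftsar` implements a three-phase pipeline for this setting: spectral
encoding, PLSR modelling with cross-validated selection, and combinatorial
prediction.

## Phase 1: spectral encoding

Each residue is replaced by the value an AAindex scale assigns to it. An
AAindex entry maps the 20 standard residues to one real number describing a
physicochemical property; `parse_aaindex_db()` reads the flat-file format
and drops any entry with missing values (no imputation — an incomplete scale
cannot encode a sequence, and silently imputing would manufacture signal).

The encoded signal $s_0, \dots, s_{N_0-1}$ is zero-padded to the next power
of two $N$ (325 &rarr; 512) and transformed:

$$S_k = \sum_{n=0}^{N-1} s_n \, e^{-2 i \pi k n / N}, \qquad k = 0, \dots, N/2.$$

The feature vector is $|S_k|$ (257 features for a 325-residue protein).
Padding serves two purposes: it enables the radix-2 FFT and gives sequences
of different lengths a common feature dimension. Because the input is real,
the upper half of the spectrum is the mirror image of the lower half and is
discarded; the DC bin is kept.

The magnitude spectrum deliberately discards phase, making the
representation insensitive to *where* a property pattern sits in the
sequence while retaining *which* periodicities it has. The flip side is that
a single substitution perturbs every bin — which is precisely why the model
is non-additive across mutations (see below).

Three conventions are ambiguous in this family of methods, so all are
explicit configuration (`spectrum_config()`) rather than hidden choices:

* `spectrum`: `"magnitude"` ($|S_k|$, default) or `"power"` ($|S_k|^2$).
* `standardize`: how the encoded signal is normalized against the 20 index
  values. The default `"zscore"` subtracts their mean and divides by their
  population SD (denominator 20), so scales living on wildly different
  numeric ranges (hydropathy vs. volume) produce comparable signals and one
  shared affine map is applied to every sequence. `"center"` and `"none"`
  are available for sensitivity analysis.
* the padded length is always taken from the wild type, so every variant of
  a study shares one feature dimension (substitution variants preserve
  length by construction; indels are out of scope).

One side effect worth knowing: with `"center"`, a hypothetical sequence
whose residues all share one index value still yields a non-flat spectrum,
because the constant (centered, non-zero) signal against the padded zeros
forms a step edge. That is a property of padding, not a bug; it is asserted
in the test suite on a worked example.

## Phase 2: PLSR with LOOCV selection

With 13 samples and 257 features, ordinary regression is hopeless;
partial least squares regression is the standard workhorse for such
$n \ll p$ spectral problems. `fit_plsr()` implements PLS1 via NIPALS:
sequential latent components maximizing predictor-response covariance,
predictors column-centered, response centered. For a univariate response the
NIPALS weight iteration converges in one exact step, so the implementation
extracts each component directly; extraction stops early if the response is
fully deflated (relative cutoff $10^{-12}$), and a request beyond that point
reuses the deepest fitted component — further components carry no response
covariance. Columns are *not* scaled to unit variance by default: many
padded-spectrum columns have near-zero variance and dividing by it amplifies
noise (`scale_x = TRUE` exposes the alternative).

At full rank the PLS fit coincides with least squares; the test suite
verifies this equivalence against a normal-equations oracle, which pins the
implementation without relying on another PLS library.

Model quality is estimated by leave-one-out cross-validation. Two metrics
summarize a model of $S$ samples with held-out predictions $\hat y_i$:

$$R^2 = \mathrm{cor}(y, \hat y)^2, \qquad
  \mathrm{cvRMSE} = \sqrt{\tfrac{1}{S}\sum_i (y_i - \hat y_i)^2}.$$

$R^2$ is computed on the LOOCV predictions, not the training fit. The
latent-component count is chosen by `select_n_components()`: grid
$1, \dots, \min(10, S-2, p)$, smallest cvRMSE wins, ties go to fewer
components. The winning grid entry's metrics are reported as-is — there is
no second, outer cross-validation loop. With a dozen samples a nested CV is
too unstable to be informative; the price is a modest optimism in the
reported $R^2$/cvRMSE, which the scan report flags. Likewise, scanning
hundreds of indices and reporting the winner involves no multiplicity
correction: the top of the ranking is a *selection*, not an unbiased
generalization estimate.

`scan_indices()` runs this per candidate index and ranks by cvRMSE
ascending (ties: $R^2$ descending, then accession). A full AAindex release
(~550 usable scales) against a 13 &times; 257 problem takes well under a
minute per hundred indices on one CPU; each index costs
$S$ NIPALS fits of a $(S{-}1) \times 257$ matrix per grid pass.

## Phase 3: combinatorial prediction

`fit_final_model()` refits on all labeled records with the selected
component count; `predict_library()` enumerates all $2^n$ mutation subsets
(deterministic order: subset size, then position-sorted signature), builds
each variant's spectrum with the model's own index and configuration,
predicts, joins measurements by mutation signature, and ranks by predicted
activity (ties: fewer mutations first, then signature). Training-set rows
are flagged so a training fit is not misread as generalization; variants
predicted above the best measurement are flagged as the candidates worth
assaying.

Because every substitution shifts all bins of the spectrum, the model's
predicted effect of a combination is not the sum of its single-mutant
effects. This is by construction, not an afterthought: additive-effect
screening is exactly what fails in the presence of epistasis, and the test
suite includes a regression test showing
$\hat y(A \cup B) \ne \hat y(A) + \hat y(B) - \hat y(\mathrm{WT})$
on a synthetic landscape.

## The synthetic landscape generator

Real recovery tests need a landscape whose truth is known everywhere.
`generate_landscape()` mimics the target study's shape by default — a
325-residue wild type, 6 mutations, 13 labeled records (WT, every single,
6 random multi-mutant combinations) — with a true activity that is exactly
linear in the generating index's spectrum:
$y(v) = \beta_0 + \beta \cdot \mathrm{spectrum}(v)$, plus optional i.i.d.
Gaussian noise.

Scales are chosen to look like a small thermostability panel: true
activities have SD `effect_scale = 12` minutes and minimum
`activity_floor = 5` minutes (half-lives are positive); the default noise
`sigma = 0.7` minutes matches the replicate SDs (0.5&ndash;0.9&nbsp;min)
such panels report.

The key design decision is how $\beta$ is drawn. A generic sparse vector in
257 dimensions is not identifiable from 13 records, so no estimator could
recover it and a "recovery test" against it would measure luck, not
correctness. Instead the generator draws a sparse seed over
`n_active_features` bins and projects it onto the span of the leading
`n_latent_dims` (default 3) principal directions of the labeled design's
centered spectra. The truth then lives in the part of feature space the
design actually probes, and with `sigma = 0` the pipeline is *expected* to
recover the generating index and reproduce the exact truth ranking of all
$2^n$ variants — any failure indicates a defect. Three latent dimensions is
deliberately below the 12 degrees of freedom of the design so that every
leave-one-out fold can still see the whole structure.

What the generator consequently does **not** emulate: real landscapes whose
activity depends on spectrum directions the panel never varies, non-linear
or non-spectral genotype-phenotype maps, mechanistic (biophysical)
epistasis, and heteroscedastic or non-Gaussian assay error. Passing the
recovery tests therefore certifies the machinery, not the scientific
adequacy of spectral-linear models for any particular protein.

Two statistical behaviors of the benchmark are worth knowing:

* *Decoy competitiveness.* A decoy index's spectra also vary with which
  mutations are present, so a decoy can fit a mostly-additive landscape
  almost as well as the generator; with 5 random decoys the generating index
  wins the scan in most but not all landscapes. The fixed-seed recovery test
  checks the typical case; the exact-ranking property is the robust one.
* *Leverage folds.* In a WT + singles + few-combos design, a mutation with
  an outsized spectral delta that happens to appear in no sampled
  combination is supported by exactly one record; that record's LOOCV fold
  is then genuinely unpredictable, and for such landscapes (roughly one in
  ten) the noiseless LOOCV $R^2$ collapses even though the full-data fit and
  ranking remain exact. Small panels in the wild have the same pathology —
  a variant whose information no other variant shares cannot be
  cross-validated.

## Numerical choices

* Deflation cutoff $10^{-12}$ (relative) in NIPALS; component extraction is
  deterministic, no random initialization anywhere in the fit.
* Degenerate responses (zero variance) are an error by default;
  `allow_degenerate = TRUE` returns the constant model, which the LOOCV
  grid uses so that a pathological fold cannot abort a scan.
* $R^2$ is undefined when either vector is constant; inside the scan this
  is caught and reported as `NA` rather than propagated as an error.
* An index that cannot encode the sequences (e.g. a zero-variance scale
  under z-scoring) is skipped with a warning, not a scan failure.
* Ties: component counts tie toward fewer; scan rows tie by $R^2$ then
  accession; ranking ties by mutation count then signature. All outputs are
  deterministic for fixed inputs.

## Problem sizes used in the test suite

The packaged tests run the full-size design (325 residues, 6 mutations,
13 records, 64-variant library) for the recovery and noise-curve checks —
each such landscape costs a few hundred small NIPALS fits and completes in
about a second — and smaller designs (40&ndash;120 residues, 3&ndash;5
mutations) where only the mechanics are under test. Oracle checks use 200
random signals (FFT vs. a direct $O(N^2)$ DFT sum, $N \le 64$) and 50
random regression problems (PLSR at full rank vs. least squares). The
noise-monotonicity check averages LOOCV $R^2$ over ten landscapes (seeds
1&ndash;10) per noise level $\sigma \in \{0, 0.5, 2\}$ minutes.

## Known limitations

* The bundled transaminase panel ships without its wild-type sequence
  (never published alongside the measurements), so the package cannot re-fit
  that panel standalone; `inst/scripts/external_replication.R` reruns the
  full analysis once the user supplies a FASTA and an AAindex release, and
  reports — without asserting — the resulting $R^2$, cvRMSE and ranking for
  comparison with published values, which additionally depend on the exact
  AAindex release and on spectrum conventions that published descriptions
  leave open.
* Substitution variants only: no indels, no codon-level effects, no
  structure-aware features.
* Point predictions only; no uncertainty quantification. With 13 training
  points, honest prediction intervals would dwarf the effect sizes — treat
  the ranking as a screening prior, not as assay replacement.
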