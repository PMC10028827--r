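---
title: "Residence times and structure-kinetics relationships from biased unbinding trajectories"
author: "MetadKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residence times and structure-kinetics relationships from biased unbinding trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

MetadKinetics turns infrequent well-tempered metadynamics unbinding
trajectories of receptor-bound ligands (the motivating system is opioids at
the mu-opioid receptor, mOR) into three kinds of results: residence-time
estimates with reliability and uncertainty measures, unbiased free-energy
surfaces over binding-mode coordinates, and machine-learned rankings of the
residue-substituent interactions that modulate dissociation kinetics. This
vignette explains the models behind each stage, the tunable parameters, the
synthetic-data generator that stands in for trajectory data, and the
numerical choices and limitations a user should know about.

## Residence times from biased first-passage times

In infrequent metadynamics a history-dependent bias $V(s,t)$ is deposited on
a small set of collective variables (here: the ligand z position relative to
the orthosteric-site centre of mass, and the ligand-receptor contact count)
rarely enough that transition states remain essentially bias-free. Each
biased first-passage time is then mapped back to an unbiased dissociation
time through the accumulated acceleration factor

$$ t_{\mathrm{resc}} \;=\; \sum_i \Delta t_i \, e^{\beta V_i}, $$

with $\beta = 1/k_BT$ and $V_i$ the instantaneous bias at frame $i$. An
unbinding event is declared at the first frame where z exceeds 15 Angstrom;
the increment between two frames is weighted by the bias at the later frame,
so the crossing frame contributes and everything after the first passage is
ignored.

If escape is a memoryless (homogeneous Poisson) process, the rescaled times
are exponential with mean $\tau$, the residence time. `fitPoissonCDF()`
estimates $\tau$ by nonlinear least squares between the empirical CDF of the
rescaled times, evaluated at the plotting positions $(i - 0.5)/n$, and
$1 - e^{-t/\tau}$. The plotting positions avoid pinning the last order
statistic to CDF $= 1$; the protocol literature does not fix a convention,
and the estimator agrees with the exponential maximum-likelihood estimator
(the sample mean, available as `method = "mle"`) to within a few percent for
$n \ge 100$. If the one-dimensional minimisation degenerates, the sample
mean is used and the fit is flagged (`converged = FALSE`).

Reliability is assessed exactly as in the protocol this package follows: a
two-sample Kolmogorov-Smirnov test between the observed rescaled times and a
large sample (default $10^6$) drawn from the fitted exponential. The
estimate is accepted when $p > 0.05$, with a strict inequality at the
boundary; the threshold is configurable. Because $\tau$ is fitted from the
same data, this test is conservative in the direction of accepting, which
matches its intended use as a sanity check rather than a formal test.

Uncertainty is quantified by bootstrap: resamples of size 15 (the number of
simulated trajectories per ligand in the emulated protocol), 10,000 times by
default, each refitted; the reported value is the mean of the bootstrap
$\tau$ distribution and its standard error is the bootstrap standard
deviation. Whether a study reports the direct fit or the bootstrap mean is
ambiguous in practice, so `kineticsSummary()` emits both.

Units: frame times are picoseconds throughout; wall-clock unbinding times
are reported in nanoseconds and rescaled residence times in seconds, and all
downstream comparisons use $\log_{10}\tau$.

## The synthetic trajectory generator

Real inputs for this analysis require microsecond-scale biased simulations
on GPUs, so the package ships a generator
(`genUnbindingTrajectories()`) that emulates the statistical structure the
estimator relies on, with known ground truth. For each trajectory an
exponential first-passage time $T^\* \sim \mathrm{Exp}(\tau_{\mathrm{true}})$
is drawn; a deterministic scalar bias schedule is then integrated stride by
stride and the trajectory unbinds at the first stride where
$\sum \Delta t\, e^{\beta V}$ reaches $T^\*$. Only $e^{\beta V(t)}$ along the
escape path matters for rescaling, so a scalar schedule preserves exactly
what the estimator assumes while avoiding any molecular dynamics. By
construction the rescaled time recomputed from the emitted frames equals
$T^\*$ to within one stride's rescaled increment.

Defaults: deposition stride 10 ps (the emulated protocol's value), hill
height 0.05 kcal/mol per deposition, step-ramp growth capped at 25 kcal/mol,
temperature 300 K ($k_BT$ in kcal/mol; the source protocol does not state
the temperature in its main text, and 300 K is the conventional choice). The
hill height controls the discretisation bias: the expected overshoot of the
accumulated rescaled time past $T^\*$ is roughly half of one stride's
increment, about 4% of $T^\*$ at $\beta h \approx 0.08$, which keeps the
recovered $\tau$ within a few percent of truth while still unbinding within
nanoseconds of wall-clock time. A `saturating` growth model mimicking the
flattening of a well-tempered bias is available. The z trace rises
monotonically with noise from 2 Angstrom to the 15 Angstrom threshold and
the contact count is anti-correlated with z, so event detection is exercised
on realistic shapes. The generator does not emulate recrossings of the
threshold, bias deposited after the transition state, or correlated frames -
so passing recovery tests validates the estimator chain, not the physical
assumptions of infrequent metadynamics on any particular system.

## Reweighting and free-energy surfaces

Unbiased expectations are recovered from biased frames with weights
$w_i \propto e^{+\beta V_i}$ (`frameWeights()`, computed with a max-shift
for numerical stability). This is the static, instantaneous-bias form of
post-hoc reweighting commonly applied to COLVAR output; the time-dependent
correction variant is deliberately not implemented, because the downstream
comparisons here (basin positions, relative well depths within a few
kcal/mol) depend on it only weakly and the static form is exactly testable
against Boltzmann-sampled ground truth. `fes()` bins the weighted frames on
a regular grid (defaults: 0.25 Angstrom for distances, 0.5 kcal/mol for
energies, 5 degrees for angles) and reports
$F = -k_BT \ln \rho$ shifted so the occupied minimum is zero; empty bins are
flagged, never numeric.

Basins are found with a persistence-style sweep (`locateBasins()`): bins are
visited in order of increasing $F$; a bin with no lower labelled neighbour
seeds a basin, and where basins meet, the shallower is merged whenever the
saddle lies less than `depthCutoff` above its minimum. The result is one
basin per local minimum separated by at least `depthCutoff` - the same
notion of "distinct minima" used when reading binding modes off a plotted
surface. `classifyBindingMode()` then reports a mode whenever a basin
minimum falls inside a named distance window; the defaults treat an
amine-D147 distance within 4 Angstrom as the salt-bridge mode, a ligand-H297
distance within 4 Angstrom as the hydrogen-bond mode, and the 7-9 by
13-15 Angstrom box describing a loosely bound buprenorphine-like state.
Window bounds are configurable because binding-mode boxes are usually
defined graphically on a plotted surface rather than numerically.

## Structure-kinetics machine learning

The feature-building stage consumes long-format interaction-energy tables:
one row per (frame, residue, substituent) with the substituent classes R1,
R2, R4 of the 4-anilidopiperidine scaffold. Frames past the exit threshold
(z > 15 Angstrom) are excluded, mirroring the restriction to the bound
portion of the trajectories. Pairs are filtered on two reweighted
statistics: the largest absolute per-ligand mean energy must reach
`magnitudeCutoff` (default 1 kcal/mol) and the across-ligand standard
deviation of those means must reach `spreadCutoff` (default 0.25 kcal/mol).
Protocols of this kind state only that pairs are filtered on the magnitude
of the interaction energies and on their distributions across compounds;
these two rules are the minimal formalisation of that idea, and reproducing
any particular surviving-pair identity list is out of scope since it
depends on trajectory data that is not distributed.

Augmentation is a block-mean bootstrap (`augmentDataset()`): each row is the
per-pair mean over a freshly drawn block of frames (default 100) of one
ligand, 200 rows per ligand, with the ligand's $\log_{10}\tau$ as target.
Block means preserve each ligand's location while creating within-ligand
variance - the minimal structure that makes a row-level 80:20 split
meaningful. The row-level split produces near-perfect test scores
because test rows share their ligand with training rows; `splitBy = "ligand"` is available for an honest
generalisation-to-new-ligands estimate and is deliberately not the default,
since the aim here is feature ranking, not prospective prediction.

Four tree ensembles are trained, configured for parity with the
sklearn-style regressors that auto-ML tools wrap: random forest
(`randomForest`, all features per split as in `RandomForestRegressor`),
extremely randomized trees (`ranger` with `splitrule = "extratrees"`, all
features per split, no bootstrap), gradient boosting and extreme gradient
boosting (both `xgboost`; the former with the classic shallow-tree,
unregularised configuration plus a tuned per-split feature-subsampling
option mirroring `max_features`, the latter with xgboost's native defaults
plus a tuned per-tree column-subsampling option). Hyperparameters are tuned
by 10-fold cross-validation on the training portion only, over a small
grid: 100 or 300 trees for the bagged models; learning rate 0.05 or 0.1 and
feature subsampling 1 or 0.5 for the boosted models. The subsampling axis
matters: on clustered augmented data, deterministic greedy boosting can
converge on training rows yet interpolate poorly in the gaps between ligand
clusters, and cross-validation tends to select the stochastic
configuration, which generalises into the $r^2 \ge 0.99$, RMSE $< 0.1$
regime this class of models is expected to reach on such data. Auto-ML
tuning spaces are rarely printed in full, so the grid here is a package
design choice.

Importance is measured two ways. Permutation importance is the decrease in
the held-out coefficient of determination when one feature column is
shuffled (mean over 5 shuffles); a feature the model never splits on scores
exactly zero. Additive attributions decompose each prediction into a base
value plus per-feature contributions: exact TreeSHAP for the
xgboost-backed models (via `predcontrib`), and exact tree-path (Saabas)
attributions for random forest and extremely randomized trees, with internal
node values reconstructed as count-weighted means of descendant leaf values
so the decomposition telescopes exactly to the model prediction. Local
accuracy therefore holds to double precision for the bagged models and to
float32 resolution (about $10^{-5}$ relative at this problem scale) for the
xgboost backends, whose tree values and predictions are single precision.

The whole protocol (optional re-augmentation, re-split, training, importance)
is repeated over trials (`runTrials()`; 100 in the emulated protocol) with
trial seeds derived from one master seed. Per-model scores are averaged over
trials, min-max normalised within each model, and averaged across models to
give the aggregate ranking used by `selectTopFeatures()` (default: keep the
top 15, dropping 9 of 24). Ties are broken by mean absolute attribution,
then token order. Whether the original trials re-augmented or only re-split
is not stated; both are supported (`sampledTable` vs `features` arguments).

## The synthetic feature generator and what passing means

`genFeatureDataset()` plants ground truth to which the whole ML stage can be
held: per-ligand pair means are Gaussian (stabilising planted pairs at
$-6 \pm 3$ kcal/mol, background pairs at $-2 \pm 1$ kcal/mol, frame noise
2 kcal/mol), and $\log_{10}\tau$ is an exact linear function of the planted
pairs' means (default coefficients $-0.5, -0.4, -0.35$ log10 s per kcal/mol
on H297.R4, H297.R1, W293.R1) plus Gaussian noise (default 0.05). Negative
coefficients encode the observed direction: more negative (stronger)
interaction energies lengthen residence. One decoy pair, D147.R1, receives
the largest energy magnitude ($-12 \pm 1$ kcal/mol) and zero effect,
emulating a strong anchoring interaction with no kinetic leverage - the
generator-level analogue of the common situation where the strongest
interaction (the conserved salt-bridge anchor) is not a kinetic modulator -
so importance rankings can be falsified. The planted pairs carry a wider across-ligand spread than the
background pairs by design: with only 19 ligands, a finite sample of
background means can correlate with the target by chance at $|r| \sim 0.4$,
and the planted marginal signal must dominate that level for the ground
truth to be identifiable by any marginal method (greedy trees included).
This is a deliberate identifiability condition of the generator, not a
property claimed for real interaction energies. What passing shows: the pipeline recovers planted linear
modulators from block-mean features and does not reward mere energy
magnitude. What it does not show: recovery of nonlinear or
interaction-coupled modulators, robustness to correlated frames, or
prospective accuracy for unseen ligands.

## Chemistry utilities

`tanimotoMatrix()` computes $|A \cap B| / |A \cup B|$ on binary molecular
fingerprints: circular Morgan-style radius-2 fingerprints (ECFP4, via
OpenBabel) by default, with MACCS keys and 1024-bit atom-pair fingerprints
as alternatives. Circular fingerprints resolve the local-environment change
of a quaternary R4 substitution on the piperidine, which pair-based
fingerprints largely miss. Reference similarity matrices rarely state their
fingerprint, so only ordinal patterns (e.g. R2-modified analogs being
closer to the parent fentanyl than R4-modified ones) are asserted, never
absolute cell values. The packaged 19-ligand table carries transcribed,
stereochemistry-free SMILES; the experimental kinetic and affinity columns
(tau_exp, K_d, K_i,NLX) are shipped empty because the source value tables
are not redistributable with the package - `pearsonLog()` and
`subsetExcludeR2()` operate on any user-supplied table with the same schema.
`pearsonLog()` correlates $\log_{10}x$ with $\log_{10}y$ over pairwise
complete records (exclusions are logged in the result), reporting Pearson's
r and the log-scale regression line.

## Numerical choices and degenerate inputs

* The tau fit is solved on $\log\tau$ by golden-section search over
  $\pm 7$ natural-log units around the sample mean; ties and
  non-convergence fall back to the sample mean with a flag.
* Zero-variance dissociation samples are an error in `fitPoissonCDF()` but
  fall back to the mean inside the bootstrap, so degenerate resamples do
  not abort an otherwise healthy bootstrap.
* Histogram bins must cover the data; an empty weighted histogram is an
  error rather than a silent all-NA surface.
* All randomness flows through per-call integer seeds; library code saves
  and restores the caller's RNG state, and multi-stage drivers derive
  per-stage seeds from one master seed, so every pipeline is reproducible
  end to end (the CLI logs the resolved configuration and seed).
* Problem sizes used by the shipped tests and the acceptance script - e.g.
  200 recovery replicates of 15 trajectories, $10^5$ reference draws for
  the KS test, 500-frame ligands with 200 augmented rows, 20 generator
  seeds for modulator recovery - were chosen as the smallest sizes at which
  the tested quantities are statistically stable.

## Known limitations

* The estimator chain assumes the Poisson picture holds; on real systems
  the KS reliability test is the only guard, and it has limited power at
  n = 15.
* Static reweighting ignores the time dependence of the bias; surfaces
  from strongly time-dependent biases are approximate.
* The row-level split overstates predictive accuracy for unseen ligands by
  design; use `splitBy = "ligand"` for that question.
* With only 19 ligands, recovery of every planted modulator is not
  guaranteed: in a minority of generator draws the weakest planted pair's
  marginal correlation with the target collapses by chance below the
  chance correlation of a background pair, and tree importances then rank
  a background proxy above it. The shipped recovery test quantifies this
  (the weakest modulator drops out of the top five in roughly 3 of 20
  generator seeds); it is a finite-sample property of any importance
  analysis over 19 compounds, not a defect of a particular model.
* The experimental comparison values are not shipped, so the correlation
  stage can only be exercised on synthetic or user-supplied tables.
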