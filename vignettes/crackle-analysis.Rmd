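---
title: "Fine-crackle acoustics: models, measurement conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-crackle acoustics: models, measurement conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fine crackles are short, high-pitched, discontinuous inspiratory lung
sounds heard in most patients with fibrotic interstitial lung disease.
Their acoustic properties -- how early in the inspiration they begin, how
many occur per inspiratory phase, their pitch, and the shape of the
individual transient in a time-expanded waveform -- carry information about
the underlying parenchyma, and in particular about the presence of
honeycombing on high-resolution CT, the radiological hallmark of
established fibrosis. `crackletrack` implements the complete measurement
and inference chain for this question: crackle detection in band-limited
inspiratory audio, waveform metrology, spectral percentile frequencies,
per-patient aggregation, and the biostatistics layer (group comparisons,
chance-corrected inter-rater agreement, unit-scaled logistic odds ratios,
ROC cutoff selection). A synthetic-data module generates annotated audio
and calibrated cohorts so that every stage is testable without clinical
recordings, which are not publicly available for this problem.

## The crackle model

A synthetic crackle is an exponentially damped sinusoid

$$ s(t) = A \,\sigma\, \sin(2\pi f_0 t)\, e^{-t/\tau}, \qquad t \ge 0, $$

with oscillation frequency $f_0$ (Hz), decay constant $\tau$ (s), peak
scale $A$ and polarity $\sigma = \pm 1$. This is the simplest waveform that
reproduces the deflection anatomy of a time-expanded fine crackle while
keeping every metrology target in closed form: the zero crossings sit at
$k/(2 f_0)$, so

* **IDW** (initial deflection width) $= 1/(2 f_0)$,
* **2CD** (two-cycle duration) $= 2/f_0$,
* successive deflection peaks decay in the exact ratio
  $A_{k+1}/A_k = e^{-1/(2 f_0 \tau)}$.

A fine crackle is defined by 2CD < 10 ms, i.e. $f_0 > 200$ Hz. The
measurement code never sees these formulas: it locates baseline crossings
on the sampled waveform (sub-sample, by linear interpolation) and measures
deflections between them, so the generator's closed forms act as an
independent oracle in the tests.

### Measurement conventions

Deflections are the maximal-magnitude excursions between consecutive
baseline crossings after the onset. IDW is the duration of deflection 1;
2CD runs from the onset to the end of deflection 4 (two full cycles); LDW
is the widest of deflections 1--4; A1--A3 are the peak magnitudes of
deflections 1--3, reported in normalized amplitude units (all other
analyses are scale-invariant, so absolute calibration is metadata only).
An event with fewer than four deflections inside the 25 ms analysis window
is unmeasurable and is excluded and logged rather than guessed at. These
conventions follow the classical computerized respiratory sound analysis
(CORSA) definitions; where the literature is ambiguous about the span of
2CD we fix it to deflections 1--4 from onset, consistent with the IDW/LDW
anatomy.

Onset timing within the inspiration is classified into equal thirds:
early (< 1/3), mid ([1/3, 2/3)), late (>= 2/3). The patient-level timing
label is the tercile of the *mean* relative onset of the first fine
crackle of each inspiration; modal or earliest-tercile rules are plausible
alternatives, but the mean-of-firsts rule is the simplest reproducible
reading of "onset timing of the crackles" and is what the aggregation
implements. The crackle count is the average number of fine crackles per
inspiratory phase with both recording sites pooled, which maximizes the
number of events per patient; site-stratified output can be derived from
the per-recording event files the extraction stage writes.

## Detection

The detector must find a few-millisecond transient inside breath noise
whose energy is concentrated in 100--1000 Hz -- exactly the band where the
crackle itself lives. At a realistic onset SNR (peak crackle power 10 dB
above the local noise power), an instantaneous-energy statistic has no
usable margin: colored in-band noise raises the energy floor by roughly
the ratio of the analysis band to the noise band, and we measured both a
smoothed nonlinear-energy (Teager) detector and an unwhitened
matched-template bank topping out far below acceptable recall/precision
on seeded fixtures. The shipped detector therefore:

1. **whitens** the segment against its own robust background spectrum
   (per-bin *median* amplitude over 50%-overlapped Hann blocks of 1024
   samples -- the median ignores sparse transients). The gain is real and
   applied in the frequency domain, so the operation is zero-phase and
   onset timing is untouched. A floor of 0.5% of the spectral peak
   regularizes empty bands.
2. computes the **short-window energy** (0.5 ms moving average of the
   squared whitened signal; the whitened crackle is click-like), and
3. thresholds it against a **rolling robust baseline**: blockwise median
   + 20 x MAD over 100 ms half-overlapped blocks, linearly interpolated to
   the sample grid. The rolling baseline absorbs the slow loudness
   envelope of the breath; the high multiplier reflects the heavy
   (roughly exponential) tail of a smoothed energy statistic.

Each suprathreshold run yields one candidate. The onset is the last
baseline crossing of the *raw* signal within 1.2 ms before the energy
rise; if none exists there (silent baseline), the first baseline departure
after the rise is used. Distant crossings are deliberately not chased:
slow in-band noise components cross zero only every few milliseconds and
would corrupt the timing. Candidates within a 10 ms refractory interval of
an accepted onset are merged into it (a decaying crackle tail can
re-trigger), and runs four orders of magnitude below the strongest run are
discarded as tail artifacts. On seeded fixtures (20 crackles over 8
inspirations, onset SNR 10 dB) this achieves recall and precision of
0.9--1.0 with onset errors below 1 ms, and is exact on noise-free
fixtures.

## Spectral percentiles

The inspiratory power spectrum is a Welch estimate: Hann windows of 4096
samples (~93 ms at 44.1 kHz, ~10.8 Hz resolution) with 50% overlap,
averaged modified periodograms scaled as one-sided power spectral density,
truncated to the 100--2000 Hz analysis band. The percentile frequency
$F_q$ is the smallest grid frequency at which the cumulative band power
reaches $q$ of the total (right-continuous step rule, no interpolation;
at an exact boundary the lower frequency wins). F50/F95/F99 are $F_q$ at
0.50/0.95/0.99. Patient-level values average the *spectra* over all
inspiratory segments of both sites before extracting percentiles --
averaging percentiles instead would not correspond to "total signal
power" at the patient level. The window length trades resolution against
variance; 10.8 Hz resolution is far below the group differences of
interest (~150 Hz in F99).

## The statistical chain

* Continuous features are summarized as median [IQR] (quartiles by linear
  interpolation of order statistics, `quantile` type 7) and compared with
  the Mann-Whitney U test (exact when $n_x n_y \le 400$ without ties,
  otherwise normal approximation with tie and continuity corrections).
  Categorical features use Pearson's chi-squared without continuity
  correction. No multiple-testing correction is applied, matching common
  practice for descriptive group tables; interpret the table p-values
  accordingly.
* **Gwet's AC1** quantifies inter-rater agreement for the radiological
  rating. Its chance term $p_e = \sum_c \pi_c (1 - \pi_c) / (C - 1)$
  shrinks at extreme prevalence, so AC1 remains informative where kappa
  collapses. The variance is Gwet's item-level linearized estimator and
  the 95% Wald interval is truncated above at 1.
* **Logistic regression** reports odds ratios per clinically meaningful
  unit: OR $= e^{\beta u}$ for unit scale $u$ (100 Hz for F99, 5 crackles
  for the count), with Wald 95% CIs transformed the same way. Fits are
  maximum likelihood via IRLS; on (quasi-)separation the fit is flagged
  and ORs are withheld rather than reported as astronomically unstable
  numbers. Candidate terms enter the multivariate model when their
  univariate p < 0.05; within any cluster of retained continuous terms
  with |Spearman rho| > 0.7 only one representative survives (F99 for the
  frequency cluster, otherwise the smallest univariate p). The model
  specification also accepts forced-in terms, since published multivariate
  tables often retain non-significant covariates.
* **ROC analysis** treats higher scores as more indicative of
  honeycombing, traces all distinct-score thresholds, and selects the
  cutoff minimizing the Euclidean distance to the upper-left corner
  (sensitivity 1, specificity 1), ties broken toward higher specificity.
  The reported cutoff is the midpoint between the adjacent distinct scores
  realizing the optimum -- which is how a fractional published cutoff for
  a count-valued feature arises. The AUC is trapezoidal and equals the
  rank (Mann-Whitney) statistic on tie-free data, which the tests assert.

## The synthetic cohort

Continuous features are lognormal, calibrated so the quartiles reproduce
published median [25th--75th percentile] group summaries:
$\mu = \ln(\mathrm{median})$, $\sigma = \ln(q_3/q_1) / (2 z_{0.75})$. Two
caveats are deliberate:

* A lognormal can match all three printed points only when
  $q_1 q_3 = \mathrm{median}^2$; printed one-decimal summaries need not
  satisfy this, so the calibration preserves the median and the IQR ratio
  exactly and the individual quartiles approximately.
* Two printed cells tie a quartile with the median at one-decimal
  resolution (IDW and LDW in the non-honeycombing group); the tied
  quartile is nudged by half the printed resolution (0.05 ms) so the
  strict ordering the fit requires holds.

Within a patient, the frequency family (F50/F95/F99) shares one normal
deviate, and so does the duration family (IDW/LDW/2CD): the comonotone
draw preserves the physical orderings $F_{50} \le F_{95} \le F_{99}$ and
$\mathrm{IDW} \le \mathrm{LDW} \le \mathrm{2CD}$ and reproduces the strong
within-family correlation that the variable-selection stage is designed to
prune. Onset-timing terciles are categorical with the published group
frequencies (20/4/0 out of 24 and 12/27/8 out of 47); the honeycombing
group therefore never draws a late onset. Counts are kept continuous --
the feature is an average per inspiratory phase, so fractional values are
meaningful (published cutoffs for it are fractional).

The cohort generator emulates marginal distributions and the tercile
split; it does **not** emulate between-feature clinical correlations
(count vs. F99, say), measurement error of the extraction chain, or any
site effect. Passing tests on synthetic cohorts therefore demonstrate the
correctness of the statistical machinery under known conditions, not
clinical reproducibility: with quartile-matched lognormals the crackle
count separates the groups at an AUC around 0.8, below published clinical
separations, and the synthetic multivariate odds ratios are not expected
to match published ones.

The breath-sound generator shapes 100--1000 Hz Gaussian noise with a
half-sine loudness envelope per phase (inspiration louder than
expiration) and inserts damped-sinusoid crackles. The onset SNR is defined
as crackle peak power over the noise power in a 20 ms window centred at
the onset -- a reproducible difficulty knob for detection tests, not a
physiological claim. With finite SNR each crackle is rescaled to hit the
requested value exactly; with `snr_db = Inf` the noise is disabled.

## Numerical and interface choices

* Time is in seconds, sample 0 sits at t = 0, phase intervals are
  half-open [start, end): a 2 s phase at 44.1 kHz is exactly 88200
  samples, and a boundary sample belongs to the next phase.
* Band-limiting is an order-4 Butterworth band-pass (100--2000 Hz)
  applied forward-backward: zero phase, so onset-timing metrics carry no
  group-delay bias. Idempotence holds for content strictly inside the
  passband; energy at the -3 dB edges is attenuated again on repeated
  application, as for any finite-order filter.
* Breath phases come from the recording protocol (paced 2 s + 2 s
  breathing) or from annotation files; no envelope-based segmentation is
  attempted, because it would insert an unvalidated stage ahead of every
  timing measurement.
* Multichannel WAV inputs are rejected by default (one auscultation site
  per file under the protocol); explicit `first_channel` / `split`
  policies are available.
* All generators are pure functions of (spec, seed), and a fully
  specified pipeline configuration plus seed determines every output byte
  -- no timestamps are written -- so full-pipeline determinism is testable
  by checksum.
* Test problem sizes: 1000 random crackle shapes for metrology, 1000
  random spectra for the percentile oracle, 500 random datasets for the
  AUC-rank identity, an 8-breath 20-crackle fixture for detection, and
  default-size (71-patient, 2 audio patients) pipeline runs for the
  end-to-end determinism check.

## Known limitations

* The detector is validated against the package's own generator; real
  bedside recordings add heart sounds, friction artifacts and
  non-stationary noise that the fixture does not model.
* The waveform measurements degrade gracefully but are noisy at low SNR
  (amplitude ratios especially); patient-level medians mitigate but do
  not remove this.
* AC1 is implemented for the multi-rater categorical case with the
  standard linearized variance; exact small-sample intervals are out of
  scope.
* The logistic layer is plain maximum likelihood; penalized (Firth-type)
  fits for separable data are deliberately out of scope, and separation
  is reported, not worked around.
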