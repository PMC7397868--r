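---
title: "Methods: WCE-normalized RNA interactome capture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WCE-normalized RNA interactome capture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricactivity)
```

## The quantity being estimated

RNA interactome capture (RIC) UV-crosslinks RNA-binding proteins
(RBPs) to poly(A)+ RNA in living cells, captures the adducts on
oligo(dT) beads, and quantifies the recovered proteins by label-free
mass spectrometry. The pull-down intensity of a protein mixes its
cellular abundance with its degree of RNA association. Dividing by the
whole-cell extract (WCE) intensity of the same protein removes the
abundance component: in log2 space,

$$\mathrm{ratio}_g = \overline{\mathrm{RIC}_g} - \overline{\mathrm{WCE}_g}
  \;\approx\; \log_2(\varphi_g\,\kappa_g\,C),$$

where $\varphi_g$ is the fraction of protein $g$ bound to poly(A)+
RNA, $\kappa_g$ its UV-crosslink efficiency, and $C$ a global capture
constant that median centering absorbs. The ratio is therefore a
*relative* estimator of in vivo RNA-binding activity, confounded by
crosslinkability — it ranks proteins and detects changes, but is not
an absolute bound fraction. All processing in this package stays in
log2 intensity space; missingness is a first-class marker distinct
from zero, because a label-free MS zero denotes non-detection, not a
measured absence.

## Preprocessing

**Imputation.** Missing cells are filled with a constant background of
18 log2 units (`impute_value`), recorded in an imputed mask. The mask,
not the filled values, drives detection logic downstream. Imputation
is applied within each triplicate batch before batches are merged;
because the fill is a constant, per-batch and global application give
identical numbers, and the ordering choice is retained to make the
processing sequence explicit. Whether centering should precede or
follow imputation is not decidable from first principles; this
package imputes first, then centers, so that imputed cells participate
in the column medians exactly like measured cells.

**Median centering.** Every sample column has its median subtracted
(even count: mean of the two central values), making each column's
median exactly zero. This removes per-sample loading and capture
offsets — including the global capture constant $C$ — at the cost of
assuming that the bulk of the proteome is comparable between samples.

**A caution on imputed ratios.** After centering, the constant 18 maps
to different normalized values in RIC and WCE columns (their medians
differ), so proteins imputed in one fraction can show large spurious
ratios: a protein near the WCE detection limit that never crosslinked
can surface with a strongly *positive* RIC/WCE ratio. This is why
every result row carries a population flag (`both`, `ric_only`,
`wce_only`) from pre-imputation detection; ratios outside `both`
rest on imputed values and should be treated as qualitative.

## The moderated t-test

With three to six replicates per protein, per-protein variances are
too unstable for ordinary t-tests. The package shrinks them toward a
scaled inverse-chi-square prior with hyperparameters $(d_0, s_0^2)$,
fitted across proteins by moment matching on log variances: with
$e_g = \ln s_g^2 - \psi(d/2) + \ln(d/2)$,

$$\psi'(d_0/2) = \operatorname{var}(e) - \overline{\psi'(d/2)},
\qquad
s_0^2 = \exp\!\big(\bar e + \psi(d_0/2) - \ln(d_0/2)\big),$$

the trigamma equation solved by Newton iteration. When the observed
dispersion does not exceed the sampling term the prior is degenerate
($d_0 = \infty$, complete shrinkage, normal-distribution p-values).
Per protein,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
t_g = \frac{\bar x_g}{\tilde s_g/\sqrt n},$$

tested two-sided on $d_0 + d$ degrees of freedom. At $d_0 = 0$ this is
the ordinary one-sample t-test, which the test suite verifies to
1e-10. Proteins with zero sample variance (e.g. fully imputed groups)
are excluded from prior *fitting* but still moderated, receiving
$\tilde s^2 = d_0 s_0^2/(d_0+d)$. RIC/WCE ratios are tested as paired
per-replicate differences (the WCE aliquot is the input of the
matching pull-down); CL vs noCL contrasts are unpaired with pooled
variance on $n_1 + n_2 - 2$ df, since the designs are unbalanced
(6 crosslinked vs 3 control samples) and unpaired by nature. Both BH
("fdr") and Bonferroni adjustments are reported, via `stats::p.adjust`.

## Comparative RIC: shift coefficients

For a mutant-vs-WT comparison, each genotype's RIC/WCE ratio gets an
expectation and variance by propagating the standard errors of the
mean RIC and mean WCE signals. The default scale is the log2
difference, whose Hessian vanishes, making second-order Taylor
propagation *exact*: $E = \mu_x - \mu_y$,
$\mathrm{Var} = \sigma_x^2 + \sigma_y^2 - 2\,\mathrm{cov}$. A
linear-scale ratio engine (`propagation: linear_ratio`) implements the
full second-order machinery
($E \approx f(\mu) + \tfrac12\operatorname{tr}(H\Sigma)$,
$\mathrm{Var} \approx g^\top\Sigma g +
\tfrac12\operatorname{tr}((H\Sigma)^2)$) for users who prefer
propagating on linear intensities; its output is mapped back to log2
by the delta method. Second-order truncation is visible in the ratio
variance — at coefficients of variation of 0.1 on both inputs it
underestimates the Monte-Carlo variance by about 4%, a deficit that
grows as CV² — which is one reason the exact log2-difference scale is
the default. The covariance between mean RIC and mean WCE defaults to
zero (separate extracts); a paired-sample estimate is available via
`cov_mode: paired`.

The raw shift of protein $g$ is $E^{mut}_g - E^{wt}_g$ with standard
error $\sqrt{V^{mut}_g + V^{wt}_g}$. Shifts are then **rescaled** by a
single additive log2 constant (a multiplicative factor on the linear
scale) chosen to zero the mean shift over *crosslinked* proteins —
those detected, pre-imputation, in the RIC of both genotypes. This
implements "minimize global variance" as mean-centering of log
shifts; the constant is reported in every output row. Mean-centering
was chosen over a linear-scale least-squares factor because the
plotted and tested quantity is the log2 shift, and centering is the
variance-minimizing additive correction on that scale.

Significance comes from *pseudo-replicates*: for each protein, three
values are drawn with sample mean exactly equal to the corrected shift
and sample SD exactly equal to a target (`empirical_mvn`, the
exact-moment construction: center, rescale, shift). Because the
moments are exact, every downstream statistic is independent of the
random seed — an invariance the suite asserts to 1e-9 — and the
simulated shift is tested directly rather than simulating mutant and
WT ratios separately (the difference of two exact-moment draws would
carry the same information with extra bookkeeping). The default
pseudo-replicate SD is the propagated SE itself, the literal reading
of feeding "exact statistics from the error propagation" into an
n = 3 test; note that the resulting t equals
$\sqrt n\,\cdot$ shift/SE, i.e. it treats the SE as a per-replicate
SD. The alternative `pseudo_sd_scale: sqrt_n` multiplies the SD by
$\sqrt n$ so the ordinary t equals shift/SE exactly — the calibrated
choice if the propagated SE is trusted as the shift's standard error.
Both are exposed; the default's operating characteristics are measured
by the acceptance simulation (power 0.89, false-positive rate 0.024 at
the conditions below) rather than assumed.

## Domain classification and set statistics

High-activity and underrepresented protein sets use the ratio
thresholds >4-fold (+2 log2) and <0.25-fold (−2 log2) at p < 0.01.
Nonclassical Pfam domains with at least `min_proteins = 4` detected
member proteins are classified from the member ratio distribution:
median ≥ +2 → `classical_like`; median ≤ −2 → `substoichiometric`;
members spanning both thresholds, or an IQR wider than half the
threshold gap → `adaptive`; otherwise the side of zero decides. The
class boundaries are anchored to the same ±2 log2 cutoffs as the
set selection, since no independent boundary is defensible; they are
configurable (`class_hi`, `class_lo`). Member proteins that also carry
a classical RBD, or the cytosolic-ribosome GO annotation
(GO:0022626), are excluded from domain statistics — classical domains
would dominate the signal, and ribosomal proteins bind rRNA rather
than poly(A)+ RNA. The classical/nonclassical Pfam vocabularies ship
as editable text files under `inst/extdata/`. GO-term statistics are
deliberately descriptive fractions only; enrichment testing belongs to
dedicated GO tooling.

## Binding-curve fitting

Anisotropy follows $r = (I_\parallel - G I_\perp)/(I_\parallel + 2 G
I_\perp)$. Titrations are fitted by unweighted nonlinear least squares
to the four-parameter logistic in the increasing-curve convention

$$y = y_{min} + \frac{y_{max} - y_{min}}{1 + (x/K_d)^{-n}},$$

with $K_d$ and the Hill slope $n$ kept positive through a log
parameterization, Levenberg–Marquardt optimization, and up to three
jittered re-initializations. Starting values are the y extremes, a
log-linear interpolation of the midpoint concentration, and $n = 1$.
The default synthetic titration is a 13-point two-fold dilution from
1240 nM (≈ 0.30 nM at the bottom), mirroring a typical plate-based
series; replicate readings are averaged upstream
(`average_readings`). Degenerate inputs — fewer than 5 points, a
concentration span under one decade, a flat curve — are rejected
rather than fitted.

## What the synthetic generator emulates — and what it does not

The generator (`sim_config`, defaults in parentheses) draws per
protein a log-normal abundance (log2 mean 26, SD 3), a bound fraction
from a two-component mixture (30% "high" stratum, Beta(5,2); the rest
Beta(1.2,25), substoichiometric), a crosslink efficiency Beta(1.5,10),
and optional complex membership (150 complexes, mean size 5). Samples
follow the two-batch triplicate design — RIC and WCE in both batches,
noCL only in the first — and each log2 intensity is signal plus a
per-sample offset (SD 0.2), complex-shared noise (SD 0.5) drawn per
complex and sample, and replicate noise (SD 0.3), censored below the
detection limit (18). Replicate noise is independent between
fractions; complex-shared noise is what makes same-complex RIC/WCE
ratio profiles correlate, reproducing the empirical clustering of
complex subunits in SD-vs-ratio plots. The noise SDs and abundance
parameters are free choices tuned to plausible label-free MS
behavior, not fitted to any deposited data set.

Deliberately not modeled: peptide-level effects and protein inference,
missing-not-at-random mechanisms beyond left-censoring, per-protein
nonspecific stickiness in the noCL background (a single fraction
β = 0.005 of abundance), and MS acquisition artifacts. One structural
consequence: because the RIC signal is always the WCE signal times
$\varphi\kappa C \le 1$ plus noise, the generator produces virtually
no `ric_only` proteins, whereas real data do (independent MS sampling
of the two fractions). Passing tests therefore demonstrate the
statistical machinery under a clean generative model, not robustness
to every pathology of real MS data.

## Simulation settings behind the reported numbers

The test suite and `scripts/acceptance.R` measure, at documented
problem sizes chosen to keep a full run within a few minutes on one
CPU:

* *Ranking recovery* — generator defaults, 2000 proteins: Spearman
  correlation between true $\log_2(\varphi\kappa)$ and estimated
  ratios among `both`-flagged proteins (observed ≈ 0.99).
* *Null calibration* — 20 000 null proteins (3 RIC vs 3 WCE, i.i.d.
  normal differences) through the full pipeline: fraction p < 0.05
  ≈ 0.05, essentially no BH discoveries.
* *Prior recovery* — 2000 variances simulated hierarchically from the
  scaled inverse-chi-square prior (d0 = 4, s0² = 1, d = 2).
* *Comparative power/FDR* — 2000 proteins, 100 affected at |Δ| = 1
  log2, replicate SD 0.3, two-batch triplicate design, with censoring
  and complexes disabled so that every affected protein can carry its
  signal and tests are independent: censored proteins cannot shift,
  and with the default detection limit roughly half the affected
  low-activity proteins would be lost to imputation — a property of
  the data, not of the inference.
* *Domain classes* — planted annotation fixture on an uncensored
  simulation (same reason: censoring removes low-stratum members and
  biases mixed-domain medians upward).
* *Complex noise* — 50 seeds with complex-shared SD three times the
  replicate SD; within- vs between-complex ratio correlation compared
  by a sign-flip permutation test.
* *Binding curves* — noiseless round trip to 1e-4 relative; 100 noisy
  titrations (anisotropy SD 0.005) give a median relative Kd error of
  ≈ 6%.

## Known limitations

* RIC/WCE ratios carry the unknown crosslinkability factor
  $\kappa_g$; they are rank-valid activity estimates, not absolute
  bound fractions.
* Ratios involving imputed values are artifacts of the background
  constant and the column medians; use the population flags.
* The default comparative test inherits the $\sqrt n$ inflation of
  the literal pseudo-replicate construction; switch to
  `pseudo_sd_scale: sqrt_n` for a calibrated shift/SE statistic.
* BH adjustment assumes (positive-regression) dependence; complex-
  shared noise induces correlated tests, mildly inflating realized
  FDR in complex-rich data.
* The linear-ratio propagation engine is second-order accurate only;
  for inputs with CV ≳ 0.1 its variance is a few percent low.
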