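---
title: "Methods: locating the dose of fastest resistance evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating the dose of fastest resistance evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscope)
```

# The question and the models

`ampliscope` quantifies how the rate of antibiotic-resistance evolution
depends on drug dose. The organising concept is the *inverted-U*: selection
for resistance grows with dose while the population supplying mutants
shrinks, so a regression of any rate-of-adaptation statistic against dose is
expected to peak at an intermediate "hotspot" dose.

## Two-strain selection model

The exactly solvable model couples a susceptible strain $S$ and a resistant
mutant $R$:

$$\frac{dS}{dt} = (g(A) - d)S - \mu S, \qquad
  \frac{dR}{dt} = (\ell g(\lambda A) - d)R + \mu S,$$

with $S(0)=1$, $R(0)=0$. Here $g$ is the dose-dependent per-capita growth
rate (normalised to $g(0)=1$, strictly decreasing), $d$ a natural death
rate, $\mu$ the mutation rate, $\lambda \in (0,1)$ the dose scaling the
mutant experiences and $\ell \in (0,1)$ its fitness cost. Writing
$\theta_1 = g(A)-d-\mu$ and $\theta_2 = \ell g(\lambda A) - d$, the solution
is $S(t) = e^{\theta_1 t}$,
$R(t) = \mu(e^{\theta_1 t} - e^{\theta_2 t})/(\theta_1-\theta_2)$, and the
susceptible frequency $\rho(t) = S/(S+R)$ depends on dose only through the
selection coefficient

$$s(A) = \theta_2 - \theta_1 = \ell g(\lambda A) - g(A) + \mu .$$

Because $\theta_1 - \theta_2$ does not involve $d$, $\rho(t)$ — and hence the
dose of fastest enrichment — is independent of the susceptible strain's MIC.
This is the model's central prediction, and it is what separates the
selection-coefficient picture from classical mutant-selection-window (MSW)
reasoning, which ties selection for resistance to the window between the
ancestral MIC ($g(A) = d$) and the mutant prevention concentration
($\ell g(\lambda A) = d$).

For the exponential response $g(A) = e^{-pA}$ the maximiser of $s$ has the
closed form $A_{hot} = \ln(1/(\ell\lambda)) / (p(1-\lambda))$, positive for
any admissible $\ell, \lambda$. For Hill responses
$g(A) = 1/((A/k_{1/2})^n + 1)$ no closed form exists and `hotspot_dose()`
maximises numerically (log-spaced grid, golden-section refinement to
relative tolerance $10^{-8}$), reporting whether the maximum is interior, at
zero, or at the bracket edge.

One boundary subtlety is worth recording: MPC > MIC is *not* implied by
$\ell, \lambda < 1$ alone. For the exponential response the ratio is
$\ln(\ell/d)/(\lambda \ln(1/d))$, which drops below 1 when the fitness cost
is strong and the dose-scaling benefit weak (and the MPC does not exist at
all when $\ell < d$). The correct statement, which the tests assert, is that
MPC > MIC exactly when the mutant still has positive net growth at the
ancestral MIC, $\ell g(\lambda \cdot \mathrm{MIC}) > d$.

## Resource-limited competition

Unchecked exponential growth cannot produce density dose-responses, so a
second model imposes a shared unit carrying capacity:

$$\frac{dS}{dt} = S(1 - A - (S+R)) - \mu S, \qquad
  \frac{dR}{dt} = R(1 - (S+R)) + \mu S,$$

with dose in units of the susceptible MIC and no cost of resistance.
`simulate_competition()` integrates this with `deSolve::lsoda`
(rtol $10^{-8}$, atol $10^{-9}$; the exact-solution cross-check of the first
model demands comparable tightness). Its characteristic geometry: total
density versus dose is monotone decreasing for short treatments and
non-monotone for longer ones, and the dose at which density *changes*
fastest (the forward time-difference computed by
`dose_response_time_difference()`) climbs with treatment duration as
resistant sweeps complete at progressively higher doses. Two caveats bound
the trivial-looking limits: with $\mu = 0$ the fastest change sits at zero
dose only while the drug-free culture is still growing — after it saturates,
the remaining-growth window shifts the argmax upward even without any
resistance — and sweeps eventually complete, after which the pattern decays
again. The tests therefore pin these claims to their valid time windows.

# Phenotype statistics

## Growth models and AICc

Each well-season trace is fitted with three blank-aware models
($B_0 + rt$; $B_0 + ae^{rt}$; $B_0 + K/(1+ae^{-rt})$) and the fit with
minimal corrected AIC is kept, with
$AICc = n\ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)$ and $k$ = model parameters + 1
(Gaussian least-squares convention; the residual variance counts as a
parameter). Ties break toward fewer parameters, which also resolves the
noiseless case where two models fit exactly. The logistic model is fitted
through the self-starting four-parameter logistic (`stats::SSfpl`)
reparameterisation, falling back to bounded Levenberg–Marquardt; model fits
that fail to converge are dropped with a warning rather than silently
replaced. Blank correction subtracts the fitted $B_0$ and deliberately keeps
negative corrected values so downstream statistics see unbiased noise.

## Hill dose-responses, MIC and EAD

Replicate-mean densities at a fixed read time are fitted with
$B(A) = b_{floor} + (b_{max}-b_{floor})/(1+(A/k_{1/2})^n)$. The floor
defaults to 0 (the data the package targets rarely resolve a detection
plateau) but can be estimated. The MIC is defined as the IC99 — the dose at
which the fitted curve equals 1% of the drug-free density — and is solved
analytically from the Hill inverse; a floor above the 1% target flags the
MIC as not attained instead of extrapolating.

Confidence intervals for the MIC (and $k_{1/2}$) come from a nonparametric
bootstrap over the replicate wells (default 1000 resamples, seeded), chosen
over fit-covariance intervals because it respects the replicate structure
without linearisation. Honesty note: simulation shows percentile intervals
from $n = 8$ replicates cover the truth at roughly 86–88%, not the nominal
95% — a familiar small-sample property of the percentile bootstrap. The test
suite asserts the attainable rate; users needing calibrated small-sample
intervals should increase replication.

The effective antibiotic dose (EAD) converts an adapted population's density
$B^*$ into ancestral-dose units by inverting the ancestral Hill fit,
$A_{EAD} = B^{-1}(B^*)$: growing to the untreated ancestral density (or
beyond) means an EAD of zero, and densities at or below the fitted floor are
flagged as beyond the fitted range. EADs are computed per replicate and
summarised afterwards, so replicate spread propagates into the summary.

## Rates of adaptation

Three statistics quantify the rate of adaptation of a phenotype series
$r(t)$ over a treatment of duration $T$:

* $\alpha = (\Delta r/2)/t_a$, where $\Delta r = r(T) - r(0)$ and $t_a$ is
  the first (linearly interpolated) crossing of the half-change level.
  Endpoints are 3-point window means to damp noise; $\Delta r < 0$ yields a
  negative $\alpha$ via the downward crossing. Multiple-crossing pathologies
  error with a diagnostic rather than guessing.
* $r_e$: the maximal forward-difference per-capita growth rate of the
  *fitted* growth model over a 24-h season ($\Delta t$ = 20 min, the
  plate-reader sampling interval). Fitting first filters high-frequency
  noise that a per-capita derivative would amplify.
* $r_{auc} = B(24h)/\int_0^{24h} B\,dt$: scale-invariant, units 1/h.

A deliberate design choice governs what series $\alpha$ is applied to in the
orchestrated pipeline. The raw multi-season OD trace is a sawtooth (each
transfer dilutes 1:100 and the culture regrows), on which $\alpha$ is
maximal at *zero* dose — the drug-free culture reaches capacity within the
first season, so its half-change time is a few hours. That statistic
measures growth, not adaptation. `run_full_analysis()` therefore computes
$\alpha$ on the *season-end* density series (the dynamic dose-response data,
one point per 24-h season): at zero dose this series is flat
($\alpha \approx 0$), at lethal doses it never rises, and the inverted-U
with an interior hotspot emerges exactly where adaptation across seasons is
fastest. The per-season alternative metric (`roa_metric = "rauc"`) applies
$\alpha$ to the series of per-season $r_{auc}$ values instead.

Dose-profile classification (`inverted_u_summary()`) counts interior local
maxima of the (optionally spline-smoothed) replicate-mean profile:
`inverted_u` requires a single interior local maximum that is also the
global maximum; "L"-shapes classify as `monotone_down`, "M"-shapes as
`complex`. Dose-increment significance uses per-replicate two-sided one-sample
t-tests with no multiplicity correction by default (each increment is
reported at raw $P < 0.05$); Benjamini–Hochberg is available behind a flag.

## Oscillation periodogram

Plate-reader fluorescence traces carry a ~0.75-h electro-mechanical
oscillation of the reading device and a slower ~10-h regulatory component.
`oscillation_periodogram()` resamples onto a uniform grid, detrends by
subtracting the best-AICc growth-model fit (`detrend = "none"` reproduces
the raw variant), and reports the interior local maxima of the DFT power
spectrum ranked by power, so leakage bins of a single component are not
double-counted. Wavelength resolution is set by the window: a 24-h window
resolves the 0.75-h line exactly (bin 32) but quantises 10 h to the nearest
bin; the acceptance checks use a 168-h window where both lines land within
1–2% of their bins.

# Genomic selection proxies

## Relative copy number

For each sequenced sample, a feature's depth statistic is divided by the
genome-wide statistic of the same track, then by the identical ratio in the
ancestral sample, making the ancestral baseline 1 by construction. The
statistic is configurable (mean, median, mode, width-weighted); the default
is the mean. The choice matters quantitatively: a large amplified region
inflates a whole-genome *mean* denominator (a 10-window amplification at 3×
copies in a 100-window genome reads 2.5, not 3.0), while the median ignores
it — which is precisely why the option exists. Coordinates are 0-based
half-open throughout; the BED/bedGraph readers normalise on input and a
strict validator rejects interval sets that look 1-based inclusive.

## Amplification selection proxy

Relative copies over time are fitted with the saturating model
$F(t) = p_1(1+t)/(1+p_2(1+t))$, $p_1, p_2 \ge 0$, with time in days and
$t = 0$ at the first sequenced sample (samples at 24/72/120 h map to
$t = 0, 2, 4$). This origin makes $F(0) = p_1/(1+p_2)$ identifiable with the
near-1 baseline; the non-negativity constraint excludes the model's
singularity. Since $p_1$ enters linearly, the fit profiles it out and
minimises over $p_2$ alone on a log scale — the same least-squares objective
as a bivariate fit, but robust in the constant-$F$ limit
$p_2 \to \infty$, which flat (unamplified) tracks genuinely occupy. The
*selection proxy* is the maximum of the analytic derivative
$F'(t) = p_1/(1+p_2(1+t))^2$ over the observed span (for $p_2 > 0$, its
left endpoint).

Per gene, proxies across the dose grid are summarised by an OLS quadratic
$s(E) = aE^2 + bE + c$: the hotspot is the vertex $-b/2a$ clamped to the
dose range when the parabola opens downward, otherwise the better boundary
dose. Genes are screened by requiring the predicted maximum to exceed 3×
the *residual standard deviation* of the quadratic fit — the "3 SD"
reference population is ambiguous in general usage (residual SD, across-gene
SD, or fit SE), so the residual interpretation is implemented and the
multiplier is exposed as an argument. A quadratic is accepted from 3 doses
upward (exactly determined at 3, where the screen is vacuous).

## SNP selection and parallelism

SNP frequency trajectories (retained when their maximum observed frequency
reaches 0.05 at any timepoint — the timepoint scope of the threshold is
applied as max-over-time) are fitted with the logistic
$f(t) = 1/(1+pe^{-st})$, $p > 0$, $s$ free in sign; $s$ (per day) is the
selection proxy. Starting values are $p = (1-f_0)/\max(f_0, 10^{-3})$ and
the log-odds regression slope for $s$.

The parallelism coefficient takes each gene's frequency vector $f$ across
the $N = 7$ dosages and computes
$P(g) = \min_{\lambda>0}\lVert f - \lambda\mathbf{1}\rVert_2$ — in closed
form, the projection $\lambda^* = \max(\bar f, 0)$ — normalised by the
largest $P$ in the gene set, flagging $p(g) > 0.7$. As defined, $P$ measures
distance *from* the uniform ray, so large coefficients mark across-dose
variability even though the threshold is conventionally read as highlighting
"parallel" evolution; the definition is implemented exactly as stated, the
tension is documented, and nothing is silently inverted.

# The synthetic-data generator

`simulate_serial_transfer()` emulates the treatment design: doses 0, 5, …,
50 µg/ml, seven 24-h seasons, eight replicate wells per dose, OD (and GFP)
read every 20 min, 1:100 transfer between seasons. Within a season,
densities follow the unit-capacity competition model extended with a
copy-number ladder: the susceptible class (1 copy of the resistance operon)
mutates into 2- and then 3-copy classes, a cell with $c$ copies experiencing
dose $A/c$. Defaults, chosen once as field-realistic and frozen: ladder
mutation rate $\mu = 10^{-4}$ (amplification-scale, orders of magnitude
above point-mutation rates), `mic_scale` 30 µg/ml (one model dose unit),
growth-rate scale 0.5/h (a minimal-medium doubling time of ~1.4 h, so a
season saturates in ~10–14 h), inoculum 0.01 of capacity. Wells add a
per-well Gaussian blank (mean 0.05, SD 0.005 OD), 5% multiplicative noise,
and additive sinusoids at 10 h and 0.75 h (amplitude 0.01 OD) emulating the
instrument oscillation; GFP is proportional to
$\sum_c N_c \, c \, \beta^{c-1}$ with repression factor $\beta = 0.7$ per
extra copy, so amplified operons yield less-than-proportional expression.
With these defaults the noiseless ground truth has an interior hotspot at
25 µg/ml — just below the nominal MIC — and the generator records per-dose
season-end class densities, the resistant fraction, the noiseless
rate-of-adaptation profile and its argmax as ground truth.

`synth_coverage()` draws windowed depths negative-binomially
(mean = depth × true copies, default depth 200×, dispersion 50) with an
ancestral track at copies 1; `synth_snp_trajectories()` draws binomial
frequencies around logistic truths at a stated read depth (≥ 20, mirroring
caller thresholds), emitting sub-threshold loci so the analysis filter can
be exercised.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: regulatory feedback on expression, lag phases and
diauxie, plate effects and well-position gradients, mixed amplification
lengths or partial-window features, mapping bias and GC-dependent coverage,
linkage between SNPs, and clonal interference beyond the three-class ladder.

# Numerical choices

* $\theta_1 \approx \theta_2$ degeneracy: below $10^{-10}\max(1,|\theta_1|)$
  the exact solution switches to the limit $R = \mu t e^{\theta_1 t}$ (and
  $\rho = 1/(1+\mu t)$), removing the 0/0.
* ODE tolerances rtol $10^{-8}$ / atol $10^{-9}$ ($10^{-12}$ in the
  generator), set by the requirement that the analytic cross-check hold to
  $10^{-6}$ relative.
* Nonlinear fits use bounded Levenberg–Marquardt (`minpack.lm`) with
  deterministic multi-starts; Hill fitting starts at
  $b_{max} = \max$ density, $k_{1/2}$ = dose nearest half-max, $n = 2$ with
  three fixed jitter sets. (Multi-starts are deliberately RNG-free so the
  bootstrap's resampling stream is untouched.)
* Degenerate inputs fail loudly and specifically: constant dose-responses
  (unidentifiable Hill exponent), monotone-increasing dose-responses,
  non-positive densities under per-capita rates, all-zero SNP trajectories,
  zero-variance t-tests (p flagged undefined), empty gene sets.

# Problem sizes

The shipped test and acceptance runs use: 100 random parameter draws for the
closed-form/numeric hotspot agreement; 20 draws for ODE-oracle equivalence;
500 binomial-noise loci at depth 1000 for SNP-fitter recovery; 100 noisy
quadratic-hotspot recoveries; and 20 seeded end-to-end replicates of the
full design (11 doses × 8 wells × 7 seasons at 20-min sampling) for the
inverted-U recovery rate — sizes at which every stochastic assertion has
comfortable margin while a complete run stays in the minutes range on one
core.

# Known limitations

Beyond the generator's scope above: the theory layer treats a single mutant
class (no stochastic birth–death, no spatial gradients, no resistance costs
in the competition model); the EAD inherits any misfit of the ancestral Hill
curve; $t_a$ takes the *first* crossing, which under strong non-monotonicity
may precede the final approach; bootstrap intervals at $n = 8$ undercover as
noted; and the quadratic hotspot regression is a local summary — genes whose
proxy profile is multimodal in dose are better read from the per-dose table
than from the vertex.
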