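---
title: "Methods: density-dependent summer demography of a cyclic lemming population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-dependent summer demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lemcycle` implements the complete summer demographic analysis of a cyclic
small-mammal population monitored by live-trapping on fixed grids, together
with a synthetic-population generator that gives every estimator a
parameter-recovery test. This vignette documents the models, their
assumptions, the tunable parameters, and the numerical and design choices
that were genuinely open.

## Study design and data model

The design emulated throughout is a multi-year (16-summer) program on 2–4
rectangular trapping grids of 144 (12×12) or 96 (8×12) single-capture
live-trap stations at 30-m spacing. Each summer holds 3 primary trapping
periods (4 in the first four study years), separated by 30 days (20 days in
the four-primary era), each containing up to 10 secondary occasions. The
population is effectively closed within a primary period and open between
them (a robust design). One grid is fenced against avian and fox predation
in its later years; those grid-years form a fourth level ("exclosure") of
the trapping-grid covariate.

Capture records carry identity, station, sex, body mass, reproductive
condition (adult females, recorded from 2009 onward) and pregnancy. Age
class is assigned from body mass at first capture within a year — adult at
≥ 28 g for females and ≥ 30 g for males, boundary inclusive. An individual
that crosses the threshold later in the same summer keeps its
first-capture class (the field protocol does not dictate either
convention; a fixed within-year class avoids composition flip-flops, while
juvenile-to-adult transitions remain possible across years). Individuals
are never observed to move between grids, so an inter-grid recapture is
treated as a data error.

## SECR density estimation

Densities per sex-age class, grid and primary period come from spatially
explicit capture–recapture with a half-normal detection function,

$$g(d) = g_0 \exp\!\left(-\frac{d^2}{2\sigma^2}\right),$$

fitted by maximising the likelihood *conditional on the number of animals
detected* (Borchers–Efford style), so density never enters the
optimisation. Detection is multi-catch: per occasion an animal's per-trap
hazard is $h_k = -\log(1 - g(d_k))$, it is caught anywhere with
probability $1 - e^{-H}$, $H = \sum_k h_k$, and the trap is drawn
proportionally to $h_k$. The single-capture Longworth traps limit each
*animal* to one capture per occasion, which the multi-catch likelihood
represents exactly; it ignores trap exclusion (two animals cannot share a
trap), the standard approximation for this trap type. The synthetic
generator uses the same process, keeping generator and estimator
consistent.

Activity centres live on a habitat mask: a lattice covering the station
bounding box plus a 100-m buffer (three to four times daily movement).
Density is the Horvitz–Thompson sum $\hat D = \sum_i 1/a_i(\hat\theta)$
with $a_i$ the effective sampling area — the mask integral of the
probability of at least one detection during the session. Its variance
combines a delta-method term on (logit $g_0$, log $\sigma$) from the
numerical Hessian with a Poisson count term,
$\widehat{\mathrm{Var}}(\hat D) = \hat D^2(1/n + \mathrm{CV}_a^2)$, and the
95% interval is lognormal-based so the lower limit stays positive. The
point-estimate CI construction is not dictated by the field protocol; the
lognormal form is the standard choice for strictly positive densities.

Numerical choices:

* **Mask spacing** defaults to 10 m (≲ σ/1.5 for realistic σ); halving it
  changes $\hat D$ by < 1% (tested), and widening the buffer beyond 100 m
  changes it by < 2% at σ ≤ 33 m. Heavy resampling loops (the composition
  bootstrap inside large pipelines) may use 20-m masks; proportions are
  density ratios and are insensitive to this.
* **Starting values.** Three deterministic sigma starts (15, 30, 60 m)
  plus a data-driven start (pooled RMS deviation of captures from
  individual centroids) are screened by likelihood value; BFGS runs from
  the best, falls back to the others if it fails to converge, and ties go
  to the smallest sigma.
* **Degenerate sessions.** No detections is an error; sessions whose
  individuals are all caught exactly once carry no spatial information and
  are returned flagged non-identifiable; zero-count classes get density 0
  with no interval.

**Abundance routing.** In sessions with more than 5 distinct individuals,
each class is fitted separately; with ≤ 5 (the low phase) all classes are
pooled per grid — capture probability and sigma constant among animals —
and class densities are class counts over the common effective sampling
area. A class too thin for its own fit inside a high-abundance session
falls back to the pooled detection model and is flagged. The pooling
scope is per session; whether detection could also be shared across
primary periods within a year is left open by the protocol and not done
here.

Sessions with no spatial information at all — every animal caught
exactly once, the routine case at the cycle trough — cannot identify
(g0, σ); left to its own devices the conditional likelihood drifts to
degenerate corners (g0 → 0 with absurd densities, or σ → 0). Such
sessions get a density from the same Horvitz–Thompson formula with
detection parameters borrowed from the grid's identifiable sessions
(medians of g0 and σ), carrying the count term of the variance only,
and are flagged `borrowed_flag`. This shared-detection fallback keeps
trough densities finite and honest; without it a single unmarked-style
capture can contribute a density three orders of magnitude off, which
would corrupt every density-dependence regression downstream.

## Composition and its bootstrap

Class proportions are density shares, $p_c = D_c / \sum_c D_c$. Their
standard errors come from a 200-replicate capture-history bootstrap:
within each session, whole individual histories are resampled with
replacement keeping the sample size (histories are never altered;
duplicates get synthetic ids), the SECR analysis is repeated under the
same routing, and the SE is the standard deviation of the proportions
across replicates. In the pooled route the refitted proportions reduce
*algebraically* to class count shares — the common effective sampling area
cancels — so the refit is skipped there as an exact shortcut.
Class-separate refits are warm-started at the session's point estimates.
Replicates that fail to converge are dropped and counted.

## Robust regression with two-axis error propagation

Relationships of proportions (and survival) to density are estimated with
a Huber M-estimator linear regression (IRLS, tuning constant 1.345 for
95% Gaussian efficiency, MAD scale re-estimated per iteration,
convergence at 1e-8 coefficient change). Because both axes carry error,
coefficients come from a 2000-replicate bootstrap: each replicate
resamples points with replacement (pairs — response, density, errors,
covariates — resampled as units), then perturbs each point on the link
scales — normal on logit proportion with delta-method sd
$se_y / (y(1-y))$, normal on log density with sd $se_x / x$ — and refits.
The coefficient estimate is the replicate mean and the CI the 2.5/97.5%
quantiles; a term is "significant" when its interval excludes zero.

Boundary conventions (the link-scale randomisation is undefined at 0/1
proportions and zero density, which occurs at local extirpation):
proportions are clamped to $[0.5/201,\, 1 - 0.5/201]$ (half a count out
of the 200 composition replicates) and densities floored at 0.01
animals/ha; both are configurable. The response is modelled on the logit
scale and density enters the composition regressions untransformed (the
generator's female-share process is logit-linear in density, and the
recovery tests confirm slope recovery on that scale); the a-posteriori
survival regressions put density on the log axis.

## Apparent survival

Summer apparent survival among primary periods uses a Cormack–Jolly–Seber
likelihood conditioned on first capture, with summers treated as
independent (between-summer recaptures are ≪ 1% in this system). Unequal
intervals are standardised through monthly survival,
$\phi_{\text{interval}} = \phi_{\text{monthly}}^{\Delta t/30}$ with
$\Delta t \in \{20, 30\}$ days. Survival and detection are modelled on the
logit scale with design formulas over sex-age group, primary period
(transition), year, grid, and the group-by-primary interaction; detection
is structured by sex by default. The likelihood is fully vectorised over
unique (year, class, grid, history) groups. This CJS formulation replaces
the multi-event machinery used historically for such data; the design
structures of interest are all expressible in it.

The candidate set is ranked by AICc with effective sample size equal to
the number of released individuals (the convention is not dictated
elsewhere; released animals are the natural unit here). The selected model
is the simplest — fewest parameters — among those within 2 AICc units of
the best, avoiding uninformative parameters. Boundary cells (monthly
survival numerically 0, as in years without a single between-primary
recapture) are retained in the survival table, flagged, and excluded from
the logit-scale survival-vs-density regression, which the two-axis
bootstrap machinery above performs (survival on logit axis, density at
the start of the interval on log axis).

## Movement, reproduction, body mass

* **Movement.** Per individual and year (primaries pooled): maximum and
  mean Euclidean distance from the first-capture station to each
  subsequent capture; all-same-trap individuals get 0. Distances are
  rounded to integer metres and modelled with a negative-binomial
  log-link regression — the zeros and overdispersion make Poisson
  untenable — with log total captures as offset, against annual density
  (mean of the last two primary sessions, i.e. July and August, summed
  over classes), sex, age and grid.
* **Reproduction.** Adult females from 2009 onward, reproductive = 1;
  binomial mixed model with individual random intercepts
  (Laplace-approximated ML; adaptive quadrature available via `nAGQ`),
  fixed effects density, primary period, grid. Complete separation is
  flagged via inflated coefficients.
* **Body mass.** Daily change between consecutive primary periods:
  (mass at t+1 − mass at t) / interval days, with within-period masses
  averaged, non-consecutive recaptures ignored and pregnant females
  excluded. Linear mixed models (ML, not REML, so AICc is comparable
  across fixed structures) with individual random intercepts; every
  candidate keeps initial mass as a fixed effect. Singular random-effect
  fits are flagged and equal the fixed-effects fit.

All three analyses share the ΔAICc < 2 simplest-model selection rule with
the survival module (one implementation).

## The synthetic generator

`sim_truth()` fixes the study conditions: densities follow a
deterministic log-scale cyclic template (trough, increase, peak, decline)
with 3–4-year period scaled between 0.05 and 9 animals/ha (the ~100-fold
observed amplitude), plus lognormal year noise (sd 0.2, shared across
grids, with half-sized independent grid deviations); the generative form
of the cycle is not specified by any field source, so a fixed waveform
with noise is the package's choice. The adult-female share of density is
logit-linear in total density (slope 0.05 per animal/ha around a 0.2
baseline, giving the male-biased low-phase sex ratio); the remainder
splits 2:1:1 among adult males and juveniles. Monthly survival per class
defaults to (F.adult 0.46, M.adult 0.29, F.juvenile 0.50, M.juvenile
0.22) with a logit-scale density slope of 0.05 for adults and 0 for
juveniles; detection uses g0 = 0.3 and sigma 15 m at zero density with
log-sigma slope −0.08 per unit density (movement contracts at high
density); reproduction is logit-linear in density (slope −0.09 around
0.8) with individual heterogeneity sd 0.5; body-mass change is linear in
initial mass with a season interaction of +0.006 g/day/g. Activity
centres are uniform on grid + 100-m buffer and fixed within a summer
(movement between primaries is expressed through detection scatter only,
matching the static per-session sigma of the estimator). Within-summer
recruitment — not constrained by any stated field value — enters as a
per-primary Poisson influx at rate 0.2 of the initial session population,
80% juveniles.

What the generator does *not* emulate: winter demography, explicit
predator dynamics, within-grid habitat heterogeneity, transients or
dispersal between grids, trap saturation (two animals cannot actually
share a Longworth trap), and behavioural responses to capture. Passing
recovery tests therefore demonstrate estimator correctness under the
stated design, not robustness to these real-data complications.

## Validation scale

The test suite and the acceptance script run the estimators at reduced
but honest problem sizes chosen for a single-CPU workstation: the SECR
recovery study uses 200 sessions at D = 5/ha on the default 10-m mask
(`scripts/acceptance.R` recomputes its relative bias and interval
coverage); the regression
coverage/size studies use 60–100 meta-replicates at B = 250–300;
survival recovery uses 400 animals per class; the end-to-end study uses
16 years × 3 grids with 6 occasions per primary, composition bootstrap
B = 12 on a 25-m mask and regression B = 300. Bootstrap replicate counts
only enter standard-error precision, not point estimates, so reduced B
widens nothing systematically. Smoke-test pipelines inside the unit
suite use 2–4 years and B below 10; those runs exercise plumbing, not
statistical performance.

## Known limitations

* The multi-catch likelihood is an approximation for single-capture traps
  at very high density (trap saturation).
* Apparent survival confounds mortality with emigration; with activity
  centres fixed within summers the generator's truth is pure survival,
  so recovery tests cannot measure emigration bias.
* The composition bootstrap conditions on the observed individuals; it
  underestimates variance when n is very small (SE of a proportion from
  2 animals is crude however computed).
* Boundary survival years (no recaptures) cannot enter the logit-scale
  density regression; their exclusion slightly attenuates negative
  density dependence estimated from data that include extirpations.
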