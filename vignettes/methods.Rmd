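---
title: "Methods: space-time geostatistical estimation of treatment coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: space-time geostatistical estimation of treatment coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ortmap)
```

This vignette is the package's own account of its statistical machinery:
the generative model, the inference scheme and its approximations, the
tunable parameters with their defaults and units, the numerical choices
that matter, and what the synthetic-data tests do and do not demonstrate
about real survey data.

## 1. The estimation problem

The target is the proportion of children under 5 with diarrhoea who
received a treatment (ORS, RHF, or ORT = either), resolved by
second-administrative unit and year. Survey data supply binomial counts at
two georeferencing resolutions — GPS-located clusters and subnational
polygons — with *small denominators*: the denominator is children who had
diarrhoea in the recall window, commonly under ten per cluster. Most
district-years are unobserved, so estimates must borrow strength across
space, time and covariates, and every downstream statement (rankings,
trends, inequality, attributable deaths) needs genuine joint uncertainty,
not marginal standard errors.

## 2. Generative model and coverage surfaces

For cluster record $i$ with denominator $N_i$ and numerator $k_i$:

$$k_i \sim \mathrm{Binomial}(N_i, p_i), \qquad
\mathrm{logit}(p_i) = x_i^\top\beta + u(s_i, t_i) + e_i,$$

with a separable space-time Gaussian field and a cluster nugget:

$$\mathrm{Cov}\!\left[u(s,t),u(s',t')\right]
  = \sigma^2\,\Big(1 + \tfrac{\sqrt3\,d}{\rho_s}\Big)
    e^{-\sqrt3\,d/\rho_s}\; \rho_t^{|t-t'|},
  \qquad e_i \sim N(0, \tau^2),$$

where $d = \lVert s-s' \rVert$ in abstract cell units. Matérn smoothness
3/2 is the workhorse choice for prevalence mapping: once-differentiable
fields, a single interpretable range parameter (correlation $\approx$ 0.05
at $d=\rho_s$), and a numerically benign covariance. Separability keeps the
model honest about what survey data can identify at desk scale and permits
the Kronecker tricks used for simulation. The nugget absorbs cluster-level
overdispersion (interviewer effects, local heterogeneity) that would
otherwise corrupt the spatial range estimate.

The grid is abstract — unit cells, row-major 0-based ids, cell-centre
distances — because nothing in the method depends on real-world projection;
admin2 nests in admin1 nests in country nests in modelling region, and all
model fitting is independent per region.

**Polygon records.** A record referenced only to an admin1 polygon is tied
to its member cells by population weights. The package's likelihood
definition (`log_likelihood()`) aggregates on the *probability* scale,
$\bar p = \sum_j w_j\, \mathrm{expit}(\eta_j)$, which matches how a
polygon-level survey actually pools children. Inside the Laplace fit,
however, the polygon functional is linearized to the *logit* scale,
$\eta_{\text{poly}} = \sum_j w_j \eta_j$, so that every record remains a
linear-Gaussian functional of the latent field and the whole record vector
collapses to an $n$-dimensional Gaussian. For smooth fields and moderate
within-polygon variation the two differ at second order in the
within-polygon spread of $\eta$; we accept this bias in exchange for exact
collapsibility, and the admin2-blocked cross-validation (Section 7) is the
guard that would reveal it misbehaving.

## 3. Inference: Laplace approximation with hyperparameter mixing

Writing $g = (\beta, z)$ with $z$ the record-level latent values
($z = Au + e$, prior covariance $K = A\Sigma A^\top + \tau^2 I$), the
inner problem maximizes $\ell(g) - \tfrac12 g^\top Q g$ by damped Newton
iterations; the binomial Hessian is diagonal in the linear predictor, so
each step is one Cholesky of a $(p+n)$ matrix. The Laplace marginal
likelihood of the transformed hyperparameters
$\theta = (\log\sigma^2, \log\rho_s, \operatorname{atanh}\rho_t,
\log\tau^2)$ is maximized by Nelder–Mead, warm-starting the inner Newton
across evaluations.

Hyperparameter uncertainty is propagated by a Gaussian approximation at
the mode: a central-difference Hessian of the negative log marginal
posterior, with eigenvalues floored at 0.4 so that a direction the data do
not identify falls back to prior-scale (not unbounded) uncertainty. A set
of `n_hyper` configurations (default 15) is sampled from this Gaussian;
each gets its own Laplace fit, and posterior draws mix equally over them.
This is an empirical-Bayes scheme in the spirit of integrated nested
Laplace approximation, chosen over a fixed coarse grid because it yields
continuous credible intervals for $\rho_t$ at the same cost; the
simulation-based calibration test (25 replicate worlds) shows 92% / 96%
coverage for the intercept and $\rho_t$ at nominal 95%.

An MCMC backend (`mbg_spec(method = "mcmc")`) — elliptical slice sampling
on $g$ under its Gaussian prior, random-walk Metropolis on $\theta$ —
satisfies the same contracts and serves as an internal cross-check; it is
the slower, asymptotically exact alternative.

**Joint surface draws.** Each of the 250 draws picks a hyperparameter
sample, draws $g^\ast$ from the corresponding Gaussian, then extends the
record-level latent state to all grid cell-years by conditioning-by-kriging:
an unconditional separable-field draw (Kronecker Cholesky, spatial factor
reused per hyperparameter sample) is corrected by kriging the residuals at
the record functionals. Every draw is therefore one coherent surface, which
is what makes draw-wise aggregation, AROC and counterfactual arithmetic
valid.

**Priors** (weakly informative, on the transformed scale):
$\log\sigma^2 \sim N(\log 0.5, 1.5^2)$,
$\log\rho_s \sim N(\log 8, 1^2)$ cell units,
$\operatorname{atanh}\rho_t \sim N(0.55, 1^2)$,
$\log\tau^2 \sim N(\log 0.05, 1.5^2)$, $\beta \sim N(0, 10^2)$. On a
30-cell domain these keep ranges between a couple of cells and the domain
size and say little else.

## 4. Stacked generalisation

Non-linear covariate effects enter through stacking rather than through the
latent model. Three child learners of increasing flexibility are fitted to
the records with 5-fold cross-fitting (fold assignment at the cluster
level, seeded): ridge-penalized binomial regression (`glmnet`, penalty by
internal cross-validation), a smooth additive model on covariates plus a
thin-plate spatial term (`mgcv`, REML with shrinkage selection), and
boosted depth-2 trees (`xgboost`) on the binomial working response with
weights $N$. Out-of-fold predictions — never computed from a record's own
fold — become the observation-level design; full-data refits supply the
prediction rasters.

Two implementation choices matter for small binomial denominators. First,
the boosted learner's round count is chosen by a small internal 3-fold
cross-validation with early stopping (capped at 200) and its base score is
the pooled proportion: with a fixed large round count, boosting fits
cluster-level binomial noise and an out-of-fold prediction can drift far
from the fold mean even when no signal exists, which violates the
null-data behaviour any stacker input should have. Second, the ensembling
constraint — non-negative weights summing to one — is imposed by
minimizing out-of-fold binomial deviance over the simplex (softmax
parameterization), and the geostatistical model then receives the single
combined logit prediction as a fixed-effect covariate with a free slope.
Constraining coefficients *inside* the Gaussian fit would break the
Laplace's linear-Gaussian structure; estimating the simplex on the
cross-fitted predictions achieves the same regularisation one stage
earlier.

## 5. Definition crosswalk

RHF definitions differ across survey instruments. Surveys reporting the
same clusters under both the standard and a non-standard definition
calibrate a binomial logistic regression of standard counts on the
continuity-corrected empirical logit of the non-standard proportion,
$\mathrm{logit}(p_{\text{std}}) = a + b\,\mathrm{logit}(p_{\text{non}})$,
at the *survey* level (cluster-level pairing is rarely available in
practice, and survey-level pooling stabilises the tiny denominators). A
fitted slope that is not positive would make the adjustment non-monotone,
so it triggers a warning and an offset-only fallback ($b = 1$). Adjusted
records get $k' = \mathrm{round}(N \hat p)$ clamped to $[0, N]$, keeping
counts integral; the inverse map recovers inputs within rounding error
$0.5/N$. With fewer than two paired surveys the pipeline leaves
non-standard records unadjusted and says so — a silent error here would
bias RHF levels.

## 6. Covariate filtering

Within each modelling region, covariates are filtered for multicollinearity
by variance inflation factor at threshold 3, the conventional cut for
prediction-oriented spatial models. The procedure is greedy
backward elimination — recompute all VIFs, drop the single worst column,
repeat — which is deterministic and order-free up to the documented
tie-break (lexicographically first name among ties). Exact collinearity is
reported as an infinite sentinel rather than an error so the filter can
remove it like any other violation; a single surviving column has VIF 1 by
convention.

## 7. Validation

Cross-validation blocks at the admin2 level: all records of a unit share a
fold (polygon records via their admin1), units are dealt to 5 folds
greedily by record count after a seeded shuffle. Four metrics are reported
per fold and pooled: bias (mean error of observed proportion minus
posterior-mean coverage), RMSE, Pearson correlation, and 95% data coverage
— the share of held-out records whose count falls inside the 2.5–97.5
percentile interval of the *binomial posterior predictive* (coverage draws
pushed through $\mathrm{Binomial}(N, p)$). Latent-scale intervals would be
systematically too narrow for count data; the posterior predictive is the
only interval a held-out count can be judged against. Binomial discreteness
inflates attainable coverage slightly above the nominal level, hence the
calibration band [0.88, 0.99] used in the tests. Fold refits reuse the
stacker out-of-fold design (already cross-fitted) rather than re-running
the learners per fold; the residual optimism from this shortcut is the
price of desk-scale runtime and is shared by the large-scale frameworks
this package emulates.

## 8. Aggregation, inequality, counterfactual

Draw cubes aggregate to admin units as population-weighted means, per draw;
95% uncertainty intervals are the 2.5th/97.5th draw percentiles under the
type-7 (linear interpolation between order statistics, rank $1 + (n-1)q$)
rule — stated explicitly because percentile conventions differ and the
package's reference values depend on it. The annualised rate of change is
computed per draw on the logit scale, $(\mathrm{logit}\,p_{y_1} -
\mathrm{logit}\,p_{y_0})/(y_1-y_0)$, reported in percent, with significance
defined as the 95% interval excluding zero; a log-ratio variant is
available by argument since the choice of scale is a convention, not a
fact. Untreated-children counts multiply a fixed episodes raster by
$(1-p)$ per draw — episode counts are treated as known because their
uncertainty is not available at this stage, so those intervals understate
total uncertainty.

Within-country inequality uses three complementary measures on admin2
units: the population-weighted Gini
$G = \sum_{ij} w_i w_j |x_i - x_j| / (2\bar x_w)$ (0 = perfect equality),
absolute percentage-point deviation from the population-weighted country
mean, and relative deviation as a percent of that mean. Metrics are
computed on draw means by default; a per-draw option yields an uncertainty
interval on the Gini itself.

The counterfactual uses a linear effectiveness model
$\mathrm{reduction}(c) = \varepsilon c$ with $\varepsilon = 0.69/0.75 =
0.92$, calibrated so that 75% coverage averts 69% of diarrhoeal deaths —
the anchor the analysis itself uses; the alternative calibration in the
literature (93% at full coverage) is inconsistent with it at rounding
level, and the 0.69-at-0.75 anchor wins because the downstream numbers are
built on it. With observed deaths $D$ at coverage $c$, baseline no-ORS
deaths are $D/(1-\varepsilon c)$, deaths attributable to lack of treatment
$D\varepsilon(1-c)/(1-\varepsilon c)$, and deaths averted by a change
$c_0 \to c_1$ are $D\varepsilon(c_1-c_0)/(1-\varepsilon c_1)$ — signed, so
coverage declines show up as deaths caused. Sensitivity scenarios halve the
effect (anchoring 35% at 75% coverage) and double it (capped below 1,
since a reduction fraction cannot reach one). The model deliberately
ignores demographic and other risk-factor change: it isolates the coverage
signal and must be read as such.

## 9. The synthetic world

`simulate_world()` generates the study conditions the tests run under:
a 30×30 grid over 6 years, 3 countries × 4 admin1 × 4 admin2 in 2
modelling regions; 8 standardized smooth covariate layers (one engineered
near-collinear, to give the VIF filter work); truth surfaces from the
generative model with intercepts around −0.6 (ORS) and −1.0 (RHF),
moderate spatial structure ($\sigma^2 = 0.4$, $\rho_s = 8$ cells,
$\rho_t = 0.8$, $\tau^2 = 0.05$) and opposing trends (+0.08/yr ORS,
−0.08/yr RHF on the logit scale), emulating rising ORS and falling RHF
use; ORT defined as $1-(1-p_{\text{ORS}})(1-p_{\text{RHF}})$ so ORT
dominates ORS cell-wise by construction. Surveys sample clusters
proportionally to population with $N = 1 + \mathrm{Poisson}(\bar N - 1)$
(denominators are children with diarrhoea, hence tiny and never zero —
the shifted-Poisson form is our choice, the sources do not state one),
10% polygon records, and for RHF a 35% non-standard definition share with
a −0.5 logit offset; 80% of non-standard surveys also report the standard
module, because calibration overlap is a design feature of multi-module
surveys, and without it the crosswalk is unidentifiable. Mortality is
$\mathrm{pop} \times \text{base rate} \times (1 - 0.6\,p_{\text{ORS}})$
with base rate 0.002/child/yr, putting simulated mortality near the
2-per-1000 scale that separates high- from low-burden settings.

What passing tests on this world demonstrate: the estimator recovers known
truth under the model's own assumptions, intervals are calibrated, every
pipeline stage composes, and all arithmetic identities hold. What they do
not demonstrate: robustness to non-separable space-time structure, survey
design effects and informative cluster placement, reporting biases in
recalled treatment, real covariate measurement error, or polygon
georeferencing subtleties beyond population weighting. Real-data use should
lean on the blocked cross-validation and treat the synthetic calibration as
a necessary, not sufficient, check.

## 10. Numerical choices and problem sizes

Cholesky factorizations carry an escalating-jitter guard; AR1 correlations
are clamped inside $(-1, 1)$ after the tanh transform; learner predictions
are clipped to the logit of $[10^{-4}, 1-10^{-4}]$; AROC clips
probabilities to $[10^{-6}, 1-10^{-6}]$ with a warning. Record profiles
(shared cell-years, shared polygon-years) are deduplicated and the Matérn
factor is evaluated once per distinct cell pair per hyperparameter
evaluation, which is what makes dense-covariance inference practical at
desk scale.

The default test-suite problem sizes — chosen as the smallest instances at
which each statistical property is comfortably identified — are: 30×30
cells × 4 years × 600 clusters × 25 replicates for parameter recovery;
20×20 × 4 years × 400 records for cross-validation calibration; and the
full 30×30 × 6-year three-indicator world for the end-to-end run, fitted
per region with `optim_maxit = 60`, `n_hyper = 8` (within Monte Carlo
error of the full settings on these sizes). Runs are deterministic given
the seeds recorded in the pipeline manifest.

## 11. Known limitations

The Laplace approximation can understate skewness of hyperparameter
posteriors at very low information; the MCMC backend exists for exactly
that doubt. The logit-scale polygon linearization biases strongly
heterogeneous polygons toward their population-weighted logit mean.
Stacker generalisation error leaks into the coverage surfaces when the
learners overfit in ways 5-fold cross-fitting does not catch. Regions are
fitted independently, so cross-border smoothing is absent by design.
Episode and population rasters are treated as fixed inputs, narrowing the
untreated-children and deaths intervals. None of these are hidden: each
has a test or a documented argument that exposes the behaviour.
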