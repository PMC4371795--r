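---
title: "A normative cost-minimisation account of startle modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A normative cost-minimisation account of startle modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlemod)
```

## The decision problem

The startle reflex is a rapid protective response to a sudden stimulus that
may herald an immediate physical blow. `startlemod` treats its magnitude
$r$ as the solution of a cost-minimisation problem. Suspecting a blow $B$
with probability $P(B|X)$ given sensory input $X$, the organism minimises

$$C_{TOT}(r) = \underbrace{C_{R,d}(r) + \eta\, C_{R,f}(r)}_{\text{startle cost}}
 + P(B|X)\,\underbrace{[C_{B,d}(r) + \eta\, C_{B,f}(r)]}_{\text{blow cost}},$$

where the $d$ subscripts are direct costs (metabolic effort of the
response; tissue damage from the blow) and the $f$ subscripts are
opportunity costs — benefits forgone because ongoing behaviour is
interrupted, by the startle itself or by the blow's aftermath. The scalar
$\eta \ge 0$ models the current utility of that ongoing behaviour and
scales both opportunity terms jointly: anticipating a reward makes *both*
interruptions more expensive.

Four behavioural assumptions give the model its predictions:

1. **Additivity** — costs combine additively and are known to the agent.
   Structural here: a `cost_family` *is* an additive bundle of four
   components.
2. **Effectiveness** — a more vigorous startle reduces the cost of a blow
   but never its probability: $\frac{d}{dr}[C_{B,d} + \eta C_{B,f}] < 0$,
   and $P(B|r, X) = P(B|X)$.
3. **Joint opportunity scaling** — changing the utility of ongoing
   behaviour multiplies both opportunity costs by the same $\eta$.
   Structural: [scale_opportunity()] can only move both together.
4. **Opportunity slopes** — the startle's opportunity cost rises more
   shallowly than the blow's falls: $C_{R,f}' > 0$, $C_{B,f}' < 0$ and
   $|C_{R,f}'| < |C_{B,f}'|$.

Two monotonicity theorems follow and are what the package's property
harnesses enforce: raising $P(B|X)$ can never lower the global minimiser
$r_0$, and (given assumption 4) raising $\eta$ can never lower it either.

## Cost families and the assumption audit

No particular functional forms are implied by the assumptions, only signs
and slopes, so the package ships three parametric families and audits them
all numerically. The default `"quadratic-exponential"` family
($C_{R,d} = a_{rd} r^2$, $C_{R,f} = a_{rf} r$,
$C_{B,d} = s_{bd} e^{-k_{bd} r}$, $C_{B,f} = s_{bf} e^{-k_{bf} r}$) has a
convex rising startle cost and smoothly decaying blow costs, the shapes the
panel figures display; `"linear"` is the minimal family (useful because its
total cost is affine in $r$, forcing boundary optima); `"logistic"`
saturates at both ends. Arbitrary component functions can be supplied as
`"custom"`.

`audit_assumptions()` checks the derivative conditions by central
differences on a lattice (default 101 points, step $r_{max}/(10\,n)$),
enforcing the strict inequalities with a margin of $10^{-10}$. Because the
assumptions are strict, a flat blow cost fails — by design.

One subtlety deserves its own paragraph. The slope comparison in
assumption 4 is stated on the raw opportunity costs, but the blow's
opportunity cost only enters the objective *in expectation*, multiplied by
$P(B|X)$. The condition the $\eta$-monotonicity argument actually needs is
therefore $|C_{R,f}'| < P(B|X)\,|C_{B,f}'|$: at very low blow
probabilities a large $\eta$ mostly amplifies the startle-side opportunity
cost and can *lower* the optimum. We treat this as an applicability range
rather than a defect: `applicable_p_floor()` returns the probability ratio
$\max_r |C_{R,f}'| / \min_r |C_{B,f}'|$ above which the guarantee holds on
the whole domain, `audit_assumptions(p_min = )` audits the
expectation-weighted condition, and the property harnesses draw blow
probabilities above the floor. Food-deprivation-style scenarios that *rely*
on $\eta$ dominating are parameterised well inside the applicable range.

## The solver

`optimal_startle()` evaluates the objective on a 1024-point lattice over
$[0, r_{max}]$ and refines around the best lattice point with bounded
scalar minimisation to a tolerance of $10^{-8}$ on $r$. The lattice stage
exists because the theorems concern *global* minimisers: refinement alone
could be trapped by a local basin of a non-convex custom family. The
refined point is kept only when it strictly beats the lattice minimum, so
on plateaus ties resolve to the smallest $r$ — consistent with the
non-strict "$r_0^* \ge r_0$" form of the monotonicity results. The test
suite cross-checks the solver against an independent exhaustive
$10^4$-point grid search and against the closed form $r_0 = p/2$ of the
reduced family $C_R = r^2$, $C_B = 1 - r$.

```{r solver}
fam <- make_cost_family()
optimal_startle(fam, blow_belief(0.2))$r0
optimal_startle(fam, blow_belief(0.6))$r0   # larger blow probability, larger r0
```

## Where the blow probability comes from

Fear-potentiated startle rules out both a fixed $P(B|X)$ and one learned by
direct experience of probe-plus-CS compounds: conditioning changes the
response on the *first* probe after learning. The remaining possibility is
inference. With a forward model of probe contingencies and the
simplification that probe and CS occur independently,

$$P(B \mid S, CS) = \frac{P(S|B)\,P(B|CS)}{P(S)}, \qquad
  P(B \mid \neg S, CS) = \frac{P(\neg S|B)\,P(B|CS)}{P(\neg S)} \approx 0,$$

the second expression being near zero because a blow is almost never
unheralded ($P(\neg S|B) \approx 0$). `posterior_with_probe()`,
`posterior_without_probe()` and `posterior_context_only()` implement the
three cases; the last replaces the learned association with the context
prior $P(B)$, which is how context conditioning, prior shock exposure,
instructed fear and lighting manipulations enter the model.

Two numerical choices: the expressions are likelihood-ratio-scaled priors
and can exceed 1 for extreme parameters, so posteriors are clamped to
$[0,1]$ with a warning — shipped scenario parameters never reach the clamp,
which the test suite asserts. And "no startle is elicited" is operationalised
as the posterior falling below a configurable $\varepsilon$ (default
$10^{-3}$), since the underlying claim is qualitative.

## A continuous blow magnitude and expectation coding

For a scalar blow magnitude $b$ the blow side of the objective becomes a
bivariate cost $c_B(r, b)$ with $c_B(r, 0) = 0$ integrated over a belief
$p(B = b)$; mass not assigned to the support is the no-blow outcome,
identified with $b = 0$. Beliefs are discretised on a configurable grid
(expectations are mass-weighted sums), avoiding any commitment to a
parametric density. With a point mass the continuous model collapses to the
discrete one — the test suite re-runs the discrete properties through the
point-mass path verbatim.

The normative functional is
$\sum_b p(B=b)\, c_B(r, b)$ (`expected_blow_cost_full()`). Its sparse rival,
**expectation coding**, feeds only an expected magnitude to the cost:
$P(blow)\, c_B(r, \bar b)$ (`expected_blow_cost_expectation_coded()`). The
two coincide exactly when $c_B$ is linear in $b$ and for point masses; for
nonlinear costs Jensen's inequality fixes the direction of the error.

The shipped bivariate form,
$c_B(r, b) = b\,[1 - g_{max}\, r \cdot \mathbf{1}\{b \le b_{crit}\}]$,
makes the startle remove a fraction $g_{max} r$ of the blow cost as long as
the blow is not too strong; above the cutoff $b_{crit}$ (default 2, with
$g_{max} = 0.8$) protection vanishes entirely. The hard cutoff is
deliberate: it is the minimal shape with both a compliant regime and a
regime where the effectiveness assumption fails, and
`effectiveness_violation_ranges()` recovers the violating magnitude
interval from the numeric $\partial c_B/\partial r$ sign pattern.

## Trial-level conditioning and the medium/high US dissociation

`run_protocol()` walks a learner through an acquisition–extinction trial
sequence. On each trial the blow posterior and the optimal startle under
*both* codings are computed from the pre-trial state (the probe precedes
the outcome), then the outcome updates the learner. Learning is
deliberately minimal, because the theory specifies *what* is learned — the
association $P(B|CS)$ — not how: the default conjugate beta-Bernoulli rule
(prior $\mathrm{Beta}(1,1)$) matches the model's Bayesian framing, and
Rescorla–Wagner is available for comparison. Extinction is nothing but
association decay under non-reinforcement; no separate inhibitory process
is modelled.

The magnitude side of the learner is the scientific crux. The
full-distribution coder keeps the empirical histogram of magnitudes
observed on reinforced trials — a genuinely factorised representation of
"how likely" and "how strong". The expectation coder instead keeps a
*single scalar*, updated by the same rule toward the observed outcome
magnitude of every trial — including the zeros of omission trials. A single
scalar cannot distinguish a less probable blow from a weaker one; during
extinction it therefore drifts downwards even though no weaker blow was
ever observed. That drift is what produces the dissociation: conditioned
with a US above $b_{crit}$, the sparse expectation starts in the
ineffectiveness range (startle suppressed), decays through the cutoff while
the association is still substantial (startle *rises*), and then follows
the fading association down (startle falls). The medium-US group never
crosses the cutoff and declines monotonically, and the full-distribution
coder — whose conditional histogram stays put at the trained magnitude —
shows no rise at all, at a true-objective cost never exceeding the sparse
coder's. `davis_astrachan_scenario()` packages the comparison and labels
the extinction shapes by collapsed sign patterns of the $r_0$ series
(changes below $10^{-6}$, the solver floor, count as no change).

The forward-model defaults used in simulation, $P(S|B) = 1$ and
$P(S) = 0.96$, encode a fully heralded blow (so probe-free trials produce
an exactly zero posterior) while keeping the probe's likelihood ratio small
enough that the conjugate learner's association can never push the
posterior past 1. Trial-level response noise (multiplicative, log-normal,
seeded) exists for realistic-looking output but is off by default: the
model is normative, and the tests exercise the deterministic path.

```{r davis, eval = FALSE}
dav <- davis_astrachan_scenario()
dav$shapes
```

## Scenario catalogue

`run_scenario()` and `run_all_scenarios()` map the classic startle
paradigms onto single-axis manipulations — association ($CS^+$ vs $CS^-$),
probe omission, context prior, opportunity scale, or US magnitude — and
classify the direction of the resulting $r_0$ change ($|\Delta r_0| <
10^{-6}$ counts as "near-zero"). Scenarios whose net direction genuinely
depends on which of two opposing effects dominates (lowered danger prior
*and* raised opportunity cost, as with positively valenced anticipation)
are reported descriptively with no verdict; the food-deprivation scenario,
whose two arms *are* the dissociation, is parameterised so the prior drop
dominates in the satiated arm and the $\eta$ rise dominates in the deprived
arm. Scenario-level cost families use a smaller startle-opportunity slope
($a_{rf} = 0.02$, $s_{bf} = 2$) than the package default so that
$\eta$-axis scenarios operate far inside the applicability range discussed
above.

## What the simulations do and do not show

All inputs are synthetic by construction — the theory's claims are
qualitative and ordinal, and no empirical startle magnitudes, units or
effect sizes are modelled. The reported "startle magnitude" is the
minimiser $r_0$ itself on a normalised $[0, 1]$ domain, not an EMG or
whole-body amplitude; trajectories are noiseless normative paths, not
fits to animal data; action selection among defensive behaviours (startle
versus freezing) is out of scope, as is any learning of the forward-model
constants. Passing tests therefore certify the internal logic — the
monotonicity theorems, the Bayes arithmetic, the coding dissociation — on
the shipped functional forms, not agreement with any particular dataset.

Problem sizes are chosen to keep the full suite fast while leaving no
randomised property thinly sampled: 200 random families per monotonicity
harness against a $10^4$-point oracle, 300 forward models for the CS-alone
bounds, 50 families for discrete-model recovery, 200 beliefs for coding
agreement, and 10 + 30 trials per conditioning group. The whole test suite
runs in well under a minute.

## Known limitations

* The relation between $P(B|CS^-)$ and the pre-conditioning baseline is
  left as a free scenario parameter; the theory says only that the $CS^-$
  posterior is the smaller one.
* The conjugate learner's $\mathrm{Beta}(1,1)$ prior puts the initial
  association at 0.5; pre-conditioning startle is nonetheless zero because
  the magnitude expectation starts at zero. Stimulus-specific priors can be
  supplied through `rule_params`.
* The hard effectiveness cutoff makes $c_B$ discontinuous in $b$ at
  $b_{crit}$; the violation-range scan and the simulations only ever
  evaluate it pointwise, but a smooth plateau-then-drop variant would be
  the natural extension.
* The audit checks the configured domain $[0, r_{max}]$ only; whether a
  narrower applicability range is intended for extreme magnitudes is a
  modelling choice the user makes by setting the domain.
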