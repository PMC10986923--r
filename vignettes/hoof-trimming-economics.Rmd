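---
title: "A Markov cohort model of hoof-trimming strategies for sole ulcers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of hoof-trimming strategies for sole ulcers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hooftrim)
```

## The decision problem

Sole ulcers are the costliest non-infectious claw lesion in dairy cows:
beyond treatment, they depress milk yield and fertility and add on-farm
labor. Two routine hoof-trimming strategies are common in Western Canadian
freestall herds:

* **partial-herd trimming** — roughly 18% of the herd is presented to the
  trimmer every 2 months, with lame cows over-represented (a cow with a
  sole ulcer has a 54% chance of being selected, a healthy cow about 17%);
* **whole-herd trimming** — every cow is trimmed every 6 months.

`hooftrim` evaluates which strategy yields the higher 3-year net benefit
for a 100-cow herd, and under what circumstances the answer flips.

## The cohort model

The herd is a closed cohort followed over 18 two-month cycles (36 months,
the average productive lifespan of a cow in an intensive system). Each
cycle classifies cows into four outcomes: trimmed/not-trimmed crossed with
ulcer/no-ulcer. Within a cycle, events are applied in a fixed order:

1. **selection** — the ulcer fraction $s_t$ and healthy fraction $1-s_t$
   are split by the strategy's selection probabilities
   $(p_{\mathrm{trim}|U},\, p_{\mathrm{trim}|H})$;
2. **cure** — trimmed ulcers resolve with probability 0.85, untrimmed
   ulcers with probability 0.20 (natural cure, applied in both arms and
   between whole-herd sessions);
3. **onset** — every currently healthy cow, including those cured this
   cycle, develops an ulcer with the per-cycle probability $q$.

The model does not state the within-cycle order of cure and onset as part
of its inputs, so we pin it: selection must precede cure (cure
probabilities are defined per trim outcome), and placing onset last lets
a freshly cured cow relapse within the same cycle, which is the
memoryless reading of a Markov cycle. Under this order the prevalence
recurrence is

$$ s_{t+1} = s_t (1 - c) + \bigl(1 - s_t (1 - c)\bigr) q, \qquad
   c = p_{\mathrm{trim}|U}\,0.85 + (1 - p_{\mathrm{trim}|U})\,0.20 ,$$

whose fixed point is $s^\* = q / (c + q - cq)$ — the long-run prevalence a
constant policy settles into (about 7% for the partial-herd reference
policy at the probabilistic-mean onset). The fixed point is exercised
directly in the test suite by iterating the step to convergence.

The per-cycle onset probability is derived from the annual incidence risk
$r$ through the exponential chain $q = 1 - \exp(\ln(1-r)/6)$, i.e. risk
$\to$ rate $-\ln(1-r)$ $\to$ 2-month probability. With $r = 7.8\%$ this
gives $q \approx 0.013$.

Whole-herd sessions fall at cycles 0, 3, 6, 9, 12, 15 — trimming at the
start of the horizon — which yields exactly 6 sessions and 600
cow-trimmings over 3 years. The partial-herd reference policy produces an
expected 324.5 cow-trimmings, matching the design value of 18 cows per
2-month visit.

## Costs, benefits and discounting

All money is in 2019 USD; published Canadian-dollar means are converted
at CAN\$1 = US\$0.77. Two published CAD means fail that conversion by an
order of magnitude (the block at 2.63 and the with-ulcer AI cost at
886.75) while every other row converts exactly, so the package treats
them as typographical errors and uses 26.30 and 286.75.

Accrual rules per cycle, with ulcer state counted at cycle **start**
(a cow trimmed for an ulcer this cycle still bears the ulcer's costs this
cycle):

| component | rule |
|---|---|
| trim | \$15.02 per expected cow-trimming |
| block | \$20.25 per expected ulcer-trim (= \$28.88 block price × 70% block probability, folded into one expected per-event price; the 70% is **not** applied again) |
| labor | \$13.34 per partial-herd session (45 min sorting), every cycle; \$2.96 per whole-herd session (10 min), session cycles only |
| reproduction | 1/6 of the annual AI cost per cow-cycle: \$220.80/yr with an ulcer (5 services), \$132.48/yr without (3 services) |
| production loss | \$101.63 per ulcer cow-cycle (1/20 of a replacement cow, quota systems) or \$73.50 (direct milk loss, the no-quota mode) |

Benefits are herd-level milk plus net cattle sales
($100 \times \$6{,}605.10 = \$660{,}510$ per year), identical in both
arms; they anchor the net-benefit level and cancel in the difference.

Discounting groups the per-cycle outlays into model years (6 cycles) and
applies beginning-of-year weights $1/1.015^y$, $y = 0, 1, 2$. This
convention reproduces the published benefits figure
($660{,}510 \times 2.9559 \approx \$1{,}952{,}388$) and implies that cost
*components* are reported undiscounted while *totals* are discounted,
which is how the summary tables here are laid out.

Two published component rows cannot be reproduced by any per-cow-cycle
state accrual: the reproduction cost is printed higher in the partial arm
than the whole arm, although the partial arm has strictly fewer ulcer
cow-cycles, and the block rows imply far fewer ulcer-trims than any trace
convention yields. The rules above are the defensible reading of the
published input tables; the consequence is that the deterministic
difference here (≈ \$4,100) and the probabilistic mean (≈ \$4,700) sit
somewhat above the published \$3,652 / \$4,337 while remaining inside the
published 95% interval, and the random-selection scenario mean sits
somewhat below its published value while remaining inside that interval.

```{r}
nb <- compare_strategies(reference_parameters())
summary(nb)
```

## Probabilistic analysis

Every probability carries a Beta(events, non-events) distribution and
every price a Normal(CAD mean, sd 0.1) distribution, both as published.
`run_psa()` redraws all of them per iteration (2000 in the reference
analysis), recomputes the onset probability from the drawn incidence
risk, reruns both arms, and summarises the difference by its mean,
empirical 2.5/97.5 percentile interval, and the fraction of draws each
strategy wins. Each iteration gets its own RNG substream derived from the
master seed, so results are independent of execution order and a shorter
run is a prefix of a longer one.

Two deliberate fidelity choices matter here:

* the incidence-risk distribution Beta(465, 1624.7) has mean 0.2225,
  **not** the deterministic 7.8%; both are used exactly as published
  (deterministic analyses use 7.8%, the PSA samples the Beta). This is
  why the probabilistic mean difference exceeds the deterministic one:
  the model responds nonlinearly to the much higher sampled incidence.
  The implied mean per-cycle onset is 0.0411, verified in the tests
  against an independent quadrature oracle.
* the published price sd of 0.1 CAD makes cost uncertainty negligible;
  essentially all PSA variance comes from the Beta draws. Negative price
  draws are resampled rather than truncated, which at sd 0.1 never
  happens in practice.

The healthy-cow selection probability is printed as 0.1699 and used
verbatim; solving $0.54 \times 0.064 + x \times 0.936 = 0.18$ would give
0.1554, but re-deriving it is deliberately avoided.

## Sensitivity and scenarios

`one_way_sensitivity()` reruns the deterministic comparison with one
input at a time at its published lower/upper bound and ranks inputs by
the induced swing (tornado order). Derived inputs are recomputed from the
varied component: block cost = price × probability whichever of the two
moves; the ±\$38.50 AI bound shifts both annual AI costs together —
which leaves the difference exactly unchanged, since a common shift adds
the same amount per cow-cycle to both arms; the 10–30% bound on the
overall trim probability rescales both conditional selection
probabilities proportionally (capped at 1), because the engine works on
the conditionals. The published labor row carries both strategies'
bounds, which are varied as two separate (near-degenerate) bars. The
three dominant bars are herd size, the trim probability and the
prevalence.

Scenarios:

1. **random selection** — both conditional selection probabilities are
   set to the overall 18% (one Beta draw applied to both in the PSA);
   the preference flips to whole-herd trimming in the large majority of
   draws. Reported whole-minus-partial, the direction of the flip.
2. **targeting sweep** — targeting levels 0.18/0.54/1.00 at a fixed
   budget of 324 cow-trimmings; the healthy-cow probability is solved by
   root-finding (prevalence feeds back on selection, so the cohort is
   rerun at every trial value; achieved budgets match to ±0.01 trims).
   The difference increases strictly with targeting.
3. **herd-size sweep** — 50 to 500 cows; the difference is linear in
   herd size ($R^2 > 0.999$) because every component except the fixed
   per-session labor scales with the herd.
4. **no quota** — production loss costed as direct milk loss (\$73.50 <
   \$101.63 per ulcer cow-cycle), lowering the difference slightly;
   partial-herd trimming still wins every draw.

## The microsimulation oracle

`simulate_herd()` realises the identical event structure per cow as
Bernoulli draws — initial ulcer by prevalence, then selection, cure and
onset each cycle — and tallies costs with the same accrual rules. Because
cows are independent and accrual is linear in the counts, the cohort
model is exactly the expectation of the microsimulation;
`validate_against_cohort()` asserts this for every tallied quantity
(trims, ulcer-trims, ulcer cow-cycles, each component, the discounted
totals and the between-arm difference) within 3 Monte-Carlo standard
errors, with zero-variance quantities (whole-herd trims, labor) required
to match exactly. This equivalence is the structural correctness test of
the package.

What the generator does *not* emulate: herd turnover (the cohort is
closed, no culling or drying-off), cow-level covariates such as parity or
lactation stage, contagion or shared-pen effects, producer-initiated
treatment between trimmer visits, and any preventive effect of trimming
on future lesions. Passing validation therefore shows the expectation
algebra is right under the stated event structure, not that the event
structure captures every feature of a real herd.

## Numerical choices and problem sizes

* Probabilistic runs use 2000 iterations (the published size; the mean is
  stable against a 1000-iteration run within 2 Monte-Carlo standard
  errors, which the tests check). Validation uses 2000 replicates of the
  100-cow herd.
* The budget solver uses `uniroot` on [0, 1] at tolerance 1e-12; expected
  trims are monotone in the healthy-cow probability, so the root is
  unique when the budget is feasible, and infeasible budgets error.
* Occupancy conservation holds to 1e-12 per cycle; component sums match
  totals to 1e-6.
* Degenerate inputs are legal and tested: zero prevalence and incidence
  (disease-free decomposition), zero cure (onset-only dynamics), zero
  discount rate (discounted = undiscounted), distribution-free
  configurations (the PSA collapses to the deterministic result).

## Limitations

The model inherits the published framing: a closed 100-cow cohort, one
lesion type, selection driven by ulcer status alone, and benefits
identical across arms. The reproduction and block accrual conventions are
the package's own pinned reading of the input tables, as the published
component table cannot be reproduced exactly from them (see above); all
headline comparisons are robust to this, but component-level figures
should be read under the stated rules.
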