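---
title: "The potential propagule pressure model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The potential propagule pressure model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pppscore)
```

## The model and its assumptions

Two mechanisms move aquatic nonindigenous species on commercial vessels:
ballast water, discharged with whatever plankton it entrained at the source
port, and biofouling on the wetted hull. The likelihood of an introduction
rises with propagule supply — the number of organisms released — but actual
propagule counts are unobservable at inspection-program scale. `pppscore`
therefore scores each arrival on two *proxies*: reported ballast water
discharge volume (BWD, m³) for the ballast mechanism, and total wetted
surface area (TWSA, m²) for the biofouling mechanism.

The model rests on three assumptions worth keeping in mind:

1. **Proxy monotonicity** — more discharged water and more colonizable hull
   area mean more potential propagules. The score predicts relative
   *potential* pressure, not establishment probability.
2. **Uniform management** — every vessel is assumed compliant with local
   ballast and biofouling management requirements; suspected noncompliance
   is handled outside the score, as an unconditional priority override.
3. **Population relativity** — scores are normalized by the medians of the
   jurisdiction's own historical arrivals, so a score is meaningful only
   relative to that population.

### From gross tonnage to TWSA

For the six common commercial types (general cargo, passenger, RO-RO,
bulker, container, tanker), wetted surface area is estimated from gross
tonnage, a free, universally published size measure, via a per-type power
law `WSA = m·GT^b` with packaged coefficients (see
`vessel_type_params()`). Gross tonnage is dimensionless and is used as-is;
no unit conversion is attempted. Unmanned barges and articulated tug-barges
(ATBs) vary too much in hull form for a tonnage regression, so their WSA is
computed per hull with the Holtrop wetted-surface approximation from
waterline length, beam, draft, and the midship/block/waterplane
coefficients (`compute_direct_wsa()`).

WSA is then inflated by the type's niche-area proportion,
`TWSA = WSA·(1 + N_p)`, because sea chests, rudders, bow thrusters and
similar protected niches accumulate disproportionate biofouling.

### The score

Given a historical population's median discharge `medBWD` and median TWSA
`medTWSA`, each arrival scores

```
PPP = BWD / medBWD + TWSA / medTWSA
```

The score is unitless, additive in its two components, exactly 2 for an
arrival at both medians, and reduces to the biofouling component for the
many arrivals that discharge nothing. Daily arrivals are ranked by score
and the top `capacity` (default 6/day) flagged high priority; cumulative
sums of the score and its components by port, vessel type or period show
where pressure concentrates.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `m`, `b` per type | – | packaged table | fleet-scale WSA–GT regressions; refit with `refit_regression()` for another fleet |
| `niche_proportion` | – | 0.07–0.27 by type | measured niche fraction of WSA; passenger vessels are highest (0.27) |
| barge/tug niche | – | 0.033 + 0.25 | applied per component by default (see below) |
| `capacity` | arrivals/day | 6 | a realistic daily boarding capacity for a mid-sized program; fully configurable |
| `bwd_policy` | – | `"discharging"` | median discharge over discharging arrivals only (see below) |
| `median_unit` | – | `"arrival"` | each arrival is one observation in the medians |
| `min_arrivals` | arrivals | 0 (50 typical) | drop rarely visited ports from regional summaries |

## Design choices on genuinely open points

**Zero discharges and `medBWD`.** Most arrivals discharge no ballast, so
the all-arrival median discharge can be 0, which would divide the ballast
component by zero. The default policy computes `medBWD` over discharging
arrivals only. The alternative (`bwd_policy = "all"`) is implemented and
errors loudly when its median is zero rather than silently substituting a
fallback. Both policies are first-class because the choice materially
changes every ballast component, and a jurisdiction freezing a baseline
should make it deliberately.

**Per-arrival vs per-vessel medians.** "The median individual vessel
value" can be read per arrival or per unique vessel. The default treats
each arrival as one observation, consistent with a baseline built from
"historical arrivals"; `median_unit = "vessel"` takes the median over each
vessel's own median so frequent callers do not drag the baseline toward
themselves.

**Barge/tug niche proportions.** The niche values for barge+tug units are
stated per component (0.033 barge, 0.25 tug) without saying whether they
apply per component or summed on the combined area. The default applies
each proportion to its own component
(`barge·1.033 + tug·1.25`) because each value is labelled with its
component; the summed reading (`(barge+tug)·1.283`) is available as
`niche_mode = "summed"`. The two differ by under 4% for typical
barge-dominated units but are both exposed for reproducibility.

**Missing data.** A missing discharge field is treated as 0 with a logged
warning — no report of discharge is read as no discharge — while a missing
hull specification for a barge/ATB is an error for that arrival, reported
per `arrival_id`, never defaulted: inventing a hull would invent a score.
A missing compliance flag defaults to compliant, matching the model's
stated assumption.

**Tie-breaking.** Daily ranking breaks score ties by descending discharge
volume, then ascending `arrival_id`, so priority lists are bit-reproducible
across runs — an auditability requirement for a regulatory tool.

**Even-count medians** are the midpoint of the two central values (the
`stats::median()` convention); documented because frozen baselines must be
bit-reproducible.

**Standard errors** in group summaries are the sample standard deviation
of per-arrival scores divided by √n, the conventional reading of a
"± SE" summary.

## The synthetic fleet generator

`generate_fleet()` emulates the structure of a multi-year jurisdictional
arrival dataset so that every stage of the package is testable without any
external data:

- a **vessel-type mix** proportional to a real year of California arrivals
  by type (container-dominated, with tankers, bulkers, RO-ROs, passenger
  vessels, ATBs and barges);
- **log-normal gross tonnage** per type (right-skewed, as real tonnage
  distributions are), with medians chosen at field-typical values, e.g.
  ~40,000 GT for containers, ~90,000 GT for passenger vessels, ~9,000 GT
  for general cargo;
- **zero-inflated log-normal discharge**: a per-type probability of any
  discharge (bulkers high at 0.75, barges near zero at 0.05) and a
  log-normal volume given discharge — this deliberately exercises the
  `medBWD` policy branches;
- a **vessel pool** ~30% the size of the arrival count, so repeat visits
  occur and the arrivals-vs-unique-vessels distinction and first-arrival
  policy are exercised;
- **hull dimensions** for barges (long, full-bodied: block coefficient
  0.85–0.95) and tugs (short, fine: 0.50–0.65) within realistic ranges,
  constant per vessel across visits;
- a 1% noncompliance rate to exercise the override path.

These values were chosen once, as structural emulation of a plausible
jurisdiction; the generator is **not** a statistical fit to any real
dataset. Passing tests on synthetic fleets therefore demonstrates the
arithmetic, invariants and plumbing of the model — identities, conservation,
determinism, policy behaviour — not that any particular real-world score
distribution is reproduced. Features of real data the generator does not
emulate include seasonality, port-by-type specialization (e.g. a bulk port
receiving bulkers almost exclusively), tonnage–discharge correlation within
type, and reporting artifacts.

Problem sizes used in the shipped checks — a 12,000-arrival four-year
population in the reproduction script, 4,000 in the trial-procedure test,
and 1,000 random days in the selection property test — are large enough for
stable summaries while keeping a full run in seconds.

## Numerical notes

- All score arithmetic is plain double precision; the dual-implementation
  oracle (`generate_known_answer_set()`) checks the production path against
  a deliberately naive re-implementation to 1e−12 relative.
- `refit_regression()` fits ordinary least squares on log–log scale; its
  r² is computed directly from residuals. Noiseless power-law data is
  recovered to better than six significant figures.
- Degenerate inputs error with typed conditions
  (`pppscore_domain_error`, `pppscore_validation_error`,
  `pppscore_scoring_error`, `pppscore_unsupported_route`) rather than
  returning sentinel values.

## Known limitations

- The packaged regression coefficients come from a fleet-scale analysis of
  United States arrivals; other regions' fleets may differ, which is why
  the parameter table is a plain-text config and a refit routine ships with
  the package.
- The score deliberately ignores voyage history, source-port environmental
  match, ballast management method, and inspection outcomes: it is the
  bottom tier of a risk-assessment hierarchy, designed for programs without
  those data. Where they exist, they belong in layers above this score.
- TWSA is a *capacity* proxy: a freshly cleaned hull and a heavily fouled
  one of equal area score identically.
- Spreadsheet input is not parsed; arrival tables are delimited text
  (export any spreadsheet to CSV first).
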