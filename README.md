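# pppscore

Proxy-based potential propagule pressure (PPP) scoring for prioritizing
commercial-vessel biosecurity inspections.

## The problem

Commercial shipping is the dominant pathway by which aquatic nonindigenous
species reach new coastal waters, via two mechanisms: organisms entrained in
**ballast water** and released on discharge, and **biofouling** attached to
the submerged hull. Regulatory programs inspect arriving vessels for
compliance with ballast-water and biofouling management requirements, but no
program can board every arrival — a jurisdiction may face thousands of
arrivals a year across many ports with staff to inspect only a fraction.
`pppscore` implements a simple, data-driven prioritization model for
jurisdictions that lack the data or resources for detailed risk profiling:
it ranks each day's arrivals by a composite proxy for the propagule pressure
the vessel *could* exert, built from only two readily available inputs per
arrival — gross tonnage and reported ballast water discharge volume.

## The model

Each arrival's wetted surface area (the submerged, colonizable hull area) is
estimated from gross tonnage GT with a per-vessel-type power law

    WSA = m · GT^b

with packaged coefficients for general cargo, passenger, RO-RO, bulker,
container, and tanker vessels (e.g. container: m = 10.66, b = 0.6501).
Unmanned barges and articulated tug-barges are too heterogeneous for a
tonnage regression; their WSA is computed directly from hull dimensions with
the Holtrop wetted-surface formula

    S = L(2T + B)·√Cm·(0.453 + 0.4425·Cb − 0.2862·Cm − 0.003467·B/T + 0.3696·Cwp) + 2.38·A_BT/Cb

The WSA is augmented by the vessel type's niche-area proportion N_p (sea
chests, rudders, thruster tunnels — biofouling hotspots):

    TWSA = WSA · (1 + N_p)

A historical arrival population supplies two medians, medBWD (over
discharging arrivals, by default) and medTWSA, and each new arrival is
scored

    PPP = BWD / medBWD + TWSA / medTWSA

The unitless score is 2 for an arrival at both medians. Daily arrivals are
ranked by score; the top *k* (default 6/day) are flagged high priority, with
suspected-noncompliant vessels always selected regardless of score.
Cumulative scores and their ballast/biofouling components can be summed by
port, vessel type, or time period to guide where inspection resources go.

## Worked example

```r
library(pppscore)

estimate_wsa_from_gt(50000, "container")
#> [1] 12093.66            # m^2 of hull below the waterline
compute_twsa(12093.66, 0.09)
#> [1] 13182.09            # plus 9% niche area

# synthetic four-year arrival population: 3 baseline years + 1 scoring year
fleet <- generate_fleet(fleet_config(n_arrivals = 4000), seed = 103)
pop   <- fleet[format(fleet$arrival_date, "%Y") <  "2018", ]
trial <- fleet[format(fleet$arrival_date, "%Y") == "2018", ]

res <- run_pipeline(pop, trial, ppp_config(capacity = 6))
res$baseline
#> PPP baseline
#>   med_bwd:  3207 m^3 (policy: discharging, unit: arrival)
#>   med_twsa: 1.037e+04 m^2
#>   window:   2015-01-01 to 2017-12-31 (3033 arrivals, 1151 discharging)
head(res$priorities[, c("date", "rank", "arrival_id", "vessel_type",
                        "ppp_score", "reason")], 3)
#>   date        rank arrival_id vessel_type ppp_score reason
#> 1 2018-01-01     1 A003034    container        1.99 score
#> 2 2018-01-02     1 A003035    bulker           1.89 score
#> 3 2018-01-02     2 A003036    container        1.33 score
head(res$group_scores, 3)
#>   port        vessel_type n_arrivals cum_bw cum_bf cum_total mean_score
#> 1 Los Angeles tanker              80   90.8   82.5      173.       2.17
#> 2 Long Beach  bulker              31  124.    38.4      162.       5.24
#> 3 Los Angeles container          108   29.0  127.       156.       1.44
```

An arrival's `ppp_score` is the sum of its `bw_component` (discharge volume
relative to the population median) and `bf_component` (TWSA relative to the
population median), so a score of 1.99 is roughly two median-vessels'
worth of potential propagule pressure arriving at once. The group table
shows where cumulative pressure concentrates and which component drives it:
at Long Beach, bulkers owe most of their cumulative score to ballast
discharge (`cum_bw` 124 vs `cum_bf` 38), while container traffic is
dominated by wetted surface area.

The same workflow is scriptable from a shell via the installed `ppp` CLI
(`exec/ppp`): `ppp baseline`, `ppp score`, `ppp prioritize`,
`ppp aggregate`, `ppp simulate`; each subcommand takes `--help`.

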