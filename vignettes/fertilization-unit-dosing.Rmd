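---
title: "Fertilization-unit dosing, production planning, and efficiency sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fertilization-unit dosing, production planning, and efficiency sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertunit)
```

## The problem

Hatcheries and germplasm repositories for aquatic species routinely apply
sperm "by eye": a volume per batch of eggs, adjusted on perceived opacity.
Because sperm is assumed abundant, doses are neither counted nor recorded,
which wastes gametes, inflates broodstock requirements, and makes
fertilization outcomes irreproducible across males, days, and facilities.
The livestock semen industry solved the analogous problem decades ago by
selling semen in standardized doses and tracking inseminations per
pregnancy; `fertunit` implements the equivalent unit-based calculus for
aquatic species, where fecundities span six orders of magnitude (about 150
eggs for a zebrafish female to 2 × 10⁷ for an eastern oyster).

The package computes three things from a species parameter profile:

1. **The fertilization unit**: the sperm dose that reliably fertilizes the
   eggs of one female, as a fresh volume or a whole number of
   cryopreservation containers.
2. **Production plans**: eggs, sperm volume, container count, and minimum
   broodstock numbers back-calculated from a target offspring count.
3. **Sensitivity of cost-normalized efficiency** to overusing or underusing
   sperm relative to the unit.

## The model

### Fertilization unit

For a female producing $N_e$ viable eggs under a protocol that applies $R$
sperm per egg, at sperm concentration $C$ (cells/mL), the fresh-sperm unit
is a volume:

$$V_\text{unit} = \frac{N_e \, R}{C} \quad \text{(mL)}.$$

For cryopreserved sperm frozen in containers of fill volume $V_c$, the unit
is a count of containers, rounded **up** so no container is partially used:

$$ n = \left\lceil \frac{N_e \, R}{C \, V_c} \right\rceil. $$

Ceiling applies only to container (and animal) counts, never to volumes or
cell counts. Exact values are the computational currency throughout the
package; rounding for display ("1.5 mL" for an exact 1.485 mL) happens only
in the report layer (`format_volume()` and friends), so machine output
(JSON/CSV) always carries full precision.

### Production back-calculation

A target of $T$ offspring surviving to a chosen life stage, with
fertilization rate $f$ and stage survival rate $s$ (both fractions in
$(0,1]$), requires

$$ N_\text{eggs} = \left\lceil \frac{T}{s\,f} \right\rceil, \qquad
   V_\text{sperm} = \frac{N_\text{eggs}\,R}{C}, \qquad
   n_\text{containers} = \left\lceil \frac{V_\text{sperm}}{V_c} \right\rceil, $$

with minimum broodstock $\lceil N_\text{eggs} / N_e \rceil$ females and
$\lceil V_\text{sperm} / V_m \rceil$ males ($V_m$ = sperm volume collected
per male). Two numerical choices here were genuinely open:

* **Egg-count carry.** The egg requirement is ceiled to a whole egg before
  the volume step (count semantics), and the exact real value is retained
  for audit. Whether to carry the exact or a rounded egg count into the
  volume step matters at display resolution: exact-carry reproduces all the
  published downstream values (395 mL and 791 straws for the catfish plan,
  47 mL and 94 straws for the oyster plan), whereas carrying a
  two-significant-figure egg count would not, so exact-carry is used.
* **No intermediate rounding** between the two divisions $T/s/f$; the
  composition is algebraically order-free.

The zebrafish profile carries a standard-operating-procedure floor of 10 on
the male pool: calculated minima say one male suffices, but stock-center
protocol pools sperm from at least 10 males. Because the floor contradicts
the calculated minimum, it is an explicit override, **off by default**
(`apply_pool_minimum = TRUE` enables it), and the unfloored value is always
reported alongside.

### Efficiency sensitivity

Unit fertilization efficiency normalizes fertilized-egg output by total
gamete cost:

$$ \mathrm{UFE} = \frac{FE}{P_s S + P_e E}, $$

with $FE$ the target number of fertilized eggs, $P_s, P_e$ the prices per
sperm cell and per egg, and $S, E$ the quantities used. Deviating from the
unit by a factor $k$ (the sperm dose becomes $kS$) scales the sperm cost
term by $k$; overuse ($k > 1$) leaves output saturated at $FE$, while
underuse ($k < 1$) additionally scales output linearly to $k\,FE$:

$$ \mathrm{UFE}_{k>1} = \frac{FE}{P_s k S + P_e E}, \qquad
   \mathrm{UFE}_{k<1} = \frac{k\,FE}{P_s k S + P_e E}, $$

and the loss statistic is
$\Delta\mathrm{UFE}\% = |\mathrm{UFE} - \mathrm{UFE}_k| / \mathrm{UFE}
\times 100$. Both branches coincide at $k = 1$, which the implementation
treats as its own case rather than assigning it arbitrarily to a branch;
sweeps (`ufe_sweep()`) insert $k = 1$ into the grid exactly so the curve is
anchored at zero.

Eliminating the prices shows that $\Delta\mathrm{UFE}\%$ depends on them
only through the **sperm cost share**
$r = P_s S / (P_s S + P_e E) \in [0, 1)$:

$$ \Delta_{k>1} = 1 - \frac{1}{1 + r(k-1)}, \qquad
   \Delta_{k<1} = 1 - \frac{k}{1 - r(1-k)}. $$

These closed forms were derived here by algebraic elimination and are
verified in the test suite against direct evaluation of the raw price
formulas; the implementation evaluates the raw formulas. The package
therefore takes $r$ as the primary knob (`gamete_cost_model(cost_share_sperm = )`),
with raw prices as an alternative entry point, because published deviation
curves print percent losses, never the underlying gamete prices.
`calibrate_cost_share()` inverts the closed forms to recover $r$ from one
observed $(k, \Delta)$ pair; $r = 1/3$ reproduces the published
catfish/oyster overuse losses (25% at $k=2$, ~57% at $k=5$, 75% at $k=10$)
and ships as the default example configuration — it is **inferred from
those losses, not a printed price assumption**.

Two published sensitivity results are deliberately not reproduced:

* The printed underuse losses at $k = 0.5$ (≈29% for catfish/oysters, ≈33%
  for zebrafish) are inconsistent with any single cost share that also
  reproduces the printed overuse losses: $r = 1/3$ gives 40% at $k = 0.5$.
  The price assumptions behind the published underuse branch are unknown;
  the package documents the discrepancy and computes the model it states.
* The least-squares-means slope comparisons between species-level curves
  are descriptive statistics over generated curves whose replicate
  structure is undefined; `ufe_sweep()` emits the curve and leaves
  comparisons to the user.

## Parameters that matter

| Parameter | Units | Catfish | Zebrafish | Oyster |
|---|---|---|---|---|
| eggs per female | eggs | 1.1 × 10⁴ | 150 | 2 × 10⁷ |
| sperm:egg ratio | cells/egg | 1.35 × 10⁵ | 2 × 10² | 15 |
| sperm concentration | cells/mL | 1 × 10⁹ | 1 × 10⁸ | 1 × 10⁸ |
| container fill volume | mL | 0.5 (straw) | 0.02 (cryo-vial) | 0.5 (straw) |
| sperm volume per male | mL | 32.5 | 0.0015 | 40 |
| fertilization rate | fraction | 0.67 | 0.60 | 0.20 |
| survival rate (stage) | fraction | 0.51 (swim-up fry) | 0.95 (28 dpf) | 0.053 (spat) |
| default target | offspring | 1 × 10⁶ | 100 | 3.3 × 10⁶ |

The zebrafish container volume is stored as the **0.02 mL fill actually
frozen**, not the 0.5 mL nominal vial capacity, because every dose
calculation uses the fill. One published narrative passage mentions the
catfish unit covering 2,700 eggs; that figure is arithmetically
inconsistent with the tabulated 1.1 × 10⁴ eggs per female and the 3-straw
unit, so the packaged profile follows the tabulated parameterization.

Sperm concentration and sperm:egg ratio dominate the unit: each is a pure
scale factor, so an order-of-magnitude error in concentration — invisible
to visual assessment in a hatchery — changes a 3-straw catfish unit into a
30-straw one (`update_profile()` supports exactly this what-if).

## Units, serialization, and degenerate inputs

Canonical units are mL and cells/mL. Profile files (YAML, JSON, or
single-row CSV) must use the canonical field names; dimensioned fields
carry a units suffix (`container_volume_ml`, `sperm_concentration_per_ml`)
and the parser rejects unknown or unsuffixed keys outright, trading
convenience for protection against silent unit errors. Dimensionless
counts, ratios and rates (`eggs_per_female`, `sperm_egg_ratio`,
`fertilization_rate`) keep semantic names; a `_frac` suffix would add noise
without preventing any plausible mistake. Microlitre input is accepted via
`*_ul` alternate keys (zebrafish volumes are naturally quoted in µL) and
converted on load; displays switch to µL below 0.01 mL. Serialization
writes numerics at 17 significant digits so profiles round-trip exactly
through all three dialects. A JSON-schema document ships under
`inst/extdata/`.

Degenerate inputs: zero eggs yield a zero unit volume and zero containers
(allowed only through direct function arguments, not through a profile,
where all counts must be positive); both gamete prices zero is an error
(undefined efficiency); `k ≤ 0` is an error. Container and animal counts
are computed as the *least integer n with n × step ≥ requirement*, with an
explicit boundary correction after the floating-point division so that the
defining inequality holds exactly as stated even when the requirement is an
exact multiple of the step (the oyster unit, 3.0 mL in 0.5 mL straws, is
such a boundary case: exactly 6, no rounding).

## What the tests do and do not show

The suite checks the three packaged parameterizations against their
published worked results end to end, property-style invariants (ceiling
oracles by brute-force search, minimality of the egg requirement,
linearity and monotonicity of the dose, branch continuity at $k = 1$,
price-scale invariance of the loss statistic, calibration round-trips to
10⁻⁹) on randomized profiles under fixed seeds, and exact serialization
round-trips. All of this validates the *calculus*, deterministically, at
desk scale (fractions of a second; randomized property checks use a few
hundred instances). It does not validate the biology: fertilization and
survival rates enter as fixed point estimates with no uncertainty, the
sperm:egg ratio is a protocol input rather than a fitted dose-response, and
the efficiency model's piecewise-linear saturation assumption ignores real
saturating fertilization kinetics — a caveat that matters most for species
like zebrafish where sperm outnumber eggs by six orders of magnitude.
Biological variance between females, males, and facilities is explicitly
out of scope: the unit exists to remove the male/dose term from that
variance, not to model it.

## Worked example

```{r}
library(fertunit)

unit_table()[, c("species", "volume_display", "unit_display",
                 "containers_exact")]

production_table()[, c("species", "eggs_display", "volume_display",
                       "containers", "min_males", "min_females")]

# overuse sensitivity calibrated from the k = 2 observation
r <- calibrate_cost_share(2, 25)
m <- gamete_cost_model(cost_share_sperm = r)
sapply(c(2, 5, 10), function(k) delta_ufe_percent(m, k))
```

## Known limitations

* Single-invocation planning only: no multi-day scheduling, inventory
  depletion, or labor modeling.
* The efficiency model is piecewise-linear by construction; no
  saturating/Hill-type fertilization response is offered.
* Cost shares must be supplied or calibrated; the package has no price
  database.
* Profiles describe species-level averages; there are no per-individual
  animal records or strain databases.
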